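test_that("compute_fai is the percent of observed trees fruiting", {
  ph <- toy_phenology(counts = c(10, 0), totals = c(100, 1522))
  fai <- compute_fai(ph)
  expect_equal(fai$fai, c(10, 0))

  # hand-counted three-month table
  ph3 <- toy_phenology(counts = c(2, 14, 7), totals = c(200, 200, 100))
  expect_equal(compute_fai(ph3)$fai, c(1, 7, 7))
})

test_that("compute_fai is invariant to row order and tree relabeling", {
  ph <- toy_phenology(counts = c(5, 9), totals = c(40, 60))
  shuffled <- ph[sample.int(nrow(ph)), ]
  relabeled <- shuffled
  relabeled$tree_id <- paste0("X", shuffled$tree_id)
  expect_equal(compute_fai(shuffled), compute_fai(ph))
  expect_equal(compute_fai(relabeled)$fai, compute_fai(ph)$fai)
  expect_error(compute_fai(rbind(ph, ph[1, ])), "duplicate")
})

test_that("fruit periods split at the reference median with ties low", {
  fai <- data.frame(month = sprintf("2012-%02d", 1:4), fai = c(1, 2, 3, 4))
  lab <- classify_fruit_periods(fai)
  expect_equal(lab$period_label, c("low", "low", "high", "high"))
  expect_equal(attr(lab, "fai_median"), 2.5)

  # observed habitat quartet
  q <- data.frame(month = sprintf("2012-%02d", 1:4),
                  fai = c(0.5, 2.44, 6.68, 14))
  labq <- classify_fruit_periods(q)
  expect_equal(attr(labq, "fai_median"), 4.56)
  expect_equal(labq$period_label, c("low", "low", "high", "high"))

  # exact ties go to the scarcity class
  tie <- data.frame(month = sprintf("2012-%02d", 1:3), fai = rep(3, 3))
  expect_true(all(classify_fruit_periods(tie)$period_label == "low"))

  expect_error(classify_fruit_periods(fai, reference_span = character(0)),
               "empty")
})

test_that("period labels are invariant to a consistent change of units", {
  fai <- data.frame(month = sprintf("2012-%02d", 1:6),
                    fai = c(0.7, 1.2, 3.1, 5.5, 9.8, 2.2))
  prop <- transform(fai, fai = fai / 100)
  expect_equal(classify_fruit_periods(fai)$period_label,
               classify_fruit_periods(prop)$period_label)
})

test_that("daily intake aggregation multiplies dry mass, fraction, kcal/g", {
  comp <- data.frame(food_item_id = "fig",
                     frac_protein = 0.10, frac_tnc = 0.50,
                     frac_lipid = 0.05, frac_ndf = 0.35)
  rec <- data.frame(individual_id = "A", date = "2012-01-05",
                    food_item_id = "fig", units = 100)
  out <- compute_daily_intake(rec, comp)
  expect_equal(unlist(out[, c("kcal_protein", "kcal_tnc", "kcal_lipid",
                              "kcal_ndf")], use.names = FALSE),
               c(40, 200, 45, 56))

  # additivity over items within a day
  comp2 <- rbind(comp, transform(comp, food_item_id = "leaf"))
  rec2 <- rbind(rec, transform(rec, food_item_id = "leaf", units = 50))
  out2 <- compute_daily_intake(rec2, comp2)
  expect_equal(out2$kcal_protein, 40 * 1.5)
  expect_equal(out2$kcal_tnc, 200 * 1.5)

  # unregistered empty days are absent; registered ones give zero rows
  expect_equal(nrow(out), 1L)
  days <- data.frame(individual_id = c("A", "A"),
                     date = c("2012-01-05", "2012-01-06"))
  out3 <- compute_daily_intake(rec, comp, days = days)
  expect_equal(nrow(out3), 2L)
  expect_equal(out3$kcal_tnc[out3$date == "2012-01-06"], 0)

  expect_error(compute_daily_intake(transform(rec, food_item_id = "bark"),
                                    comp), "bark")
  expect_error(compute_daily_intake(transform(rec, units = -1), comp),
               "negative")
})

test_that("NPe sums the non-protein components and conserves energy", {
  d <- toy_follow(protein = 100, tnc = 500, lipid = 120, ndf = 80)
  expect_equal(compute_npe(d), 700)
  expect_equal(compute_npe(toy_follow(protein = 0, tnc = 0, lipid = 0,
                                      ndf = 0)), 0)
  set.seed(42)
  many <- toy_follow(protein = runif(50, 1, 500), tnc = runif(50, 1, 3000),
                     lipid = runif(50, 1, 400), ndf = runif(50, 1, 900))
  der <- add_derived_intakes(many)
  expect_equal(der$kcal_protein + der$kcal_npe, der$kcal_total)
})

test_that("macronutrient ratios divide kcal sums and flag zero denominators", {
  d <- toy_follow(protein = 100, tnc = 770, lipid = 120, ndf = 80)
  expect_equal(compute_ratio(d, "npe", "protein"), 9.7)
  expect_equal(compute_ratio(toy_follow(tnc = 0, protein = 50), "tnc",
                             "protein"), 0)
  expect_warning(r <- compute_ratio(toy_follow(protein = 0), "tnc", "protein"),
                 "zero denominator")
  expect_true(is.na(r))
})
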