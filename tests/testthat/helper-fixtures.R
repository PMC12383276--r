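# Small in-code fixtures shared across test files.

# phenology table with a prescribed fruiting count per month
toy_phenology <- function(counts, totals) {
  do.call(rbind, lapply(seq_along(counts), function(m) {
    data.frame(tree_id = sprintf("T%03d", seq_len(totals[m])),
               month = sprintf("2012-%02d", m),
               fruiting = seq_len(totals[m]) <= counts[m])
  }))
}

# follow-day rows with explicit kcal values
toy_follow <- function(individual_id = "A", date = "2012-01-05",
                       protein = 100, tnc = 500, lipid = 120, ndf = 80,
                       full_day = TRUE) {
  data.frame(individual_id = individual_id, date = date,
             sex = "F", age_sex_class = "adult_female",
             kcal_protein = protein, kcal_tnc = tnc,
             kcal_lipid = lipid, kcal_ndf = ndf, full_day = full_day)
}

# minimal fai table with period labels
toy_fai <- function(months = c("2012-01", "2012-02"),
                    fai = c(2, 8)) {
  classify_fruit_periods(data.frame(month = months, fai = fai))
}

# hierarchical power-law data generated directly from the log-log model:
# log(%P) = c + alpha_j + L * log(E) + eps
powerlaw_data <- function(n_ind = 8, n_day = 30, L = -0.7, c0 = NULL,
                          sd_alpha = 0.08, sd_eps = 0.1, seed = 1) {
  set.seed(seed)
  c0 <- if (is.null(c0)) log(10) - L * log(2500) else c0
  id <- rep(seq_len(n_ind), each = n_day)
  alpha <- rnorm(n_ind, 0, sd_alpha)
  logE <- log(runif(n_ind * n_day, 1200, 4800))
  pctP <- exp(c0 + alpha[id] + L * logE + rnorm(n_ind * n_day, 0, sd_eps))
  E <- exp(logE)
  P <- pctP / 100 * E
  npe <- E - P
  data.frame(individual_id = sprintf("ID%02d", id), date = "2012-01-01",
             kcal_protein = P, kcal_tnc = npe * 0.6, kcal_ndf = npe * 0.3,
             kcal_lipid = npe * 0.1, full_day = TRUE)
}
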