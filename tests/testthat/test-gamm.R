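# small simulated designs; MCMC settings kept desk-scale (2 chains) for the
# module tests, with recovery at the full test profile in the acceptance suite

test_that("the spline basis spans linear functions unpenalized", {
  set.seed(1)
  x <- runif(200, 0, 10)
  bs <- build_spline_basis(x, k = 10)
  # OLS through the basis reproduces y = 2x exactly (linear null space)
  X1 <- cbind(1, bs$X)
  beta <- qr.solve(X1, 2 * x)
  expect_lt(max(abs(X1 %*% beta - 2 * x)), 1e-8)
  # and the penalty does not charge for it (nor for a constant)
  expect_lt(drop(beta[-1] %*% bs$S %*% beta[-1]) / drop(crossprod(beta[-1])),
            1e-9)
  # sine on a grid, unpenalized LS: within 0.05 everywhere on [0, 2pi]
  g <- seq(0, 2 * pi, length.out = 150)
  bg <- build_spline_basis(g, k = 10)
  Xg <- cbind(1, bg$X)
  fitted <- Xg %*% qr.solve(Xg, sin(g))
  expect_lt(max(abs(fitted - sin(g))), 0.05)

  expect_error(build_spline_basis(rep(1:5, 10), k = 10), "smaller k")
  expect_error(build_spline_basis(x, k = 3), ">= 4")
})

test_that("family selection identifies the generating distribution", {
  set.seed(2)
  y_g <- rgamma(2000, shape = 4, rate = 0.5)
  sel <- select_family(y_g)
  expect_equal(sel$family, "gamma")
  expect_equal(unname(sel$params["shape"]), 4, tolerance = 0.15)
  expect_equal(unname(sel$params["rate"]), 0.5, tolerance = 0.15)

  expect_equal(select_family(rlnorm(2000, 0, 0.5))$family, "lognormal")
  expect_equal(select_family(rnorm(2000, 10, 1))$family, "gaussian")
  expect_error(select_family(c(-1, 2, 3), candidates = c("gamma", "lognormal")),
               "non-positive")
})

test_that("a flat gaussian truth yields a smooth interval covering a constant", {
  set.seed(3)
  n <- 250
  d <- data.frame(x = runif(n, 0, 10),
                  individual_id = sample(sprintf("ID%d", 1:8), n, TRUE))
  d$y <- 5 + rnorm(n, 0, 0.5)
  sp <- gamm_spec("y", "x", "gaussian", k = 8)
  f <- fit_gamm(sp, d, chains = 2, iter = 400, warmup = 400, seed = 1)
  g <- seq(0.5, 9.5, length.out = 40)
  sm <- posterior_smooth(f, g)        # smooth component, centered at 0
  lo <- apply(sm, 2, quantile, 0.025); hi <- apply(sm, 2, quantile, 0.975)
  expect_true(all(lo <= 0 & hi >= 0))
})

test_that("a gamma-family smooth recovers the generating curve", {
  set.seed(4)
  n <- 400; J <- 16
  id <- rep(seq_len(J), each = n / J)
  x <- runif(n, 0, 10)
  alpha <- rnorm(J, 0, 0.2)
  ftrue <- function(x) 1 + 0.5 * sin(x / 10 * 2 * pi)
  y <- rgamma(n, shape = 5, rate = 5 / exp(ftrue(x) + alpha[id]))
  d <- data.frame(y = y, x = x, individual_id = sprintf("ID%02d", id))
  f <- fit_gamm(gamm_spec("y", "x", "gamma", random_slope = FALSE), d,
                chains = 2, iter = 800, warmup = 600, seed = 2)
  expect_true(f$converged)
  # central 80% of the predictor range, posterior 95% band covers the truth
  g <- seq(1, 9, length.out = 50)
  sm <- posterior_smooth(f, g, include_intercept = TRUE)
  lo <- apply(sm, 2, quantile, 0.025); hi <- apply(sm, 2, quantile, 0.975)
  covered <- mean(ftrue(g) >= lo & ftrue(g) <= hi)
  expect_gte(covered, 0.9)
  # shape parameter in the neighbourhood of the generating value
  expect_equal(mean(f$draws[, "shape"]), 5, tolerance = 0.3)
})

test_that("a decreasing bernoulli truth shows a credibly negative slope", {
  set.seed(5)
  n <- 500
  x <- runif(n, 0, 10)
  id <- sample(sprintf("ID%d", 1:10), n, TRUE)
  p <- plogis(2 - 0.6 * x)
  d <- data.frame(y = rbinom(n, 1, p), x = x, individual_id = id)
  f <- fit_gamm(gamm_spec("y", "x", "bernoulli", k = 8, random_slope = FALSE),
                d, chains = 2, iter = 500, warmup = 500, seed = 3)
  g <- seq(2, 8, length.out = 60)
  rg <- detect_nonflat_regions(finite_difference_slopes(f, g))
  expect_true(nrow(rg) >= 1)
  expect_true(all(rg$sign == "decreasing"))
  sl <- finite_difference_slopes(f, g)
  expect_true(all(colMeans(sl$slopes) < 0))
})

test_that("posterior smooths evaluate pointwise and refuse extrapolation", {
  set.seed(6)
  d <- data.frame(x = runif(150, 0, 1), individual_id = "A")
  d$y <- sin(2 * pi * d$x) + rnorm(150, 0, 0.2)
  d2 <- rbind(d, transform(d, individual_id = "B"))
  f <- fit_gamm(gamm_spec("y", "x", "gaussian", k = 6, random_slope = FALSE),
                d2, chains = 2, iter = 300, warmup = 300, seed = 4)
  g <- c(0.2, 0.5, 0.5, 0.8)
  sm <- posterior_smooth(f, g)
  expect_equal(dim(sm), c(nrow(f$draws), 4L))
  expect_identical(sm[, 2], sm[, 3])      # identical grid points
  fine <- posterior_smooth(f, seq(0, 1, by = 0.1))
  expect_equal(sm[, 1], fine[, 3])        # shared point, same values
  expect_error(posterior_smooth(f, 1.2), "extrapolates")
})

test_that("fits are reproducible under a fixed seed", {
  set.seed(7)
  d <- data.frame(x = runif(120, 0, 1), individual_id = rep(c("A", "B"), 60))
  d$y <- d$x + rnorm(120, 0, 0.3)
  sp <- gamm_spec("y", "x", "gaussian", k = 5, random_slope = FALSE)
  f1 <- fit_gamm(sp, d, chains = 2, iter = 200, warmup = 200, seed = 11)
  f2 <- fit_gamm(sp, d, chains = 2, iter = 200, warmup = 200, seed = 11)
  expect_identical(f1$draws, f2$draws)
})

test_that("posterior predictive replicates match the data on a well-specified fit", {
  set.seed(8)
  n <- 300
  d <- data.frame(x = runif(n, 0, 5), individual_id = "Z")
  d2 <- rbind(d, transform(d, individual_id = "W"))
  d2$y <- exp(0.5 + 0.2 * d2$x + rnorm(2 * n, 0, 0.4))
  f <- fit_gamm(gamm_spec("y", "x", "lognormal", k = 6, random_slope = FALSE),
                d2, chains = 2, iter = 400, warmup = 400, seed = 5)
  yrep <- posterior_predict(f, ndraws = 200, seed = 1)
  rep_means <- rowMeans(yrep)
  rep_sds <- apply(yrep, 1, sd)
  # observed statistics inside the central 95% of the replicate distribution
  expect_gt(mean(d2$y), quantile(rep_means, 0.025))
  expect_lt(mean(d2$y), quantile(rep_means, 0.975))
  expect_gt(sd(d2$y), quantile(rep_sds, 0.025))
  expect_lt(sd(d2$y), quantile(rep_sds, 0.975))
  expect_true(all(yrep > 0))             # family-link coherence
})

test_that("diagnostics flag under-sampled fits and clear clean ones", {
  set.seed(9)
  d <- data.frame(x = runif(240, 0, 1),
                  individual_id = rep(sprintf("ID%d", 1:8), 30))
  alpha <- rnorm(8, 0, 0.3)
  d$y <- 2 * d$x + alpha[as.integer(factor(d$individual_id))] +
    rnorm(240, 0, 0.3)
  sp <- gamm_spec("y", "x", "gaussian", k = 5, random_slope = FALSE)
  good <- fit_gamm(sp, d, chains = 2, iter = 2000, warmup = 2000, seed = 6)
  dg <- diagnostics(good)
  expect_lt(dg$max_rhat, 1.01)
  expect_identical(dg$divergences, 0L)
  expect_true(all(dg$pareto_k <= 0.7, na.rm = TRUE))

  bad <- fit_gamm(sp, d, chains = 2, iter = 10, warmup = 0, seed = 6)
  expect_false(diagnostics(bad, pareto = FALSE)$converged)
})

test_that("family support contracts are enforced", {
  d <- data.frame(y = c(-1, 1, 2), x = c(1, 2, 3), individual_id = "A")
  expect_error(fit_gamm(gamm_spec("y", "x", "gamma", k = 4), d),
               "strictly positive")
  d2 <- data.frame(y = c(0.2, 0.5, 2), x = c(1, 2, 3), individual_id = "A")
  expect_error(fit_gamm(gamm_spec("y", "x", "bernoulli", k = 4), d2), "0/1")
  expect_error(gamm_spec("y", "x", "poisson"), "arg")
})
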