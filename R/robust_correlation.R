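## Hierarchical Bayesian robust correlation: observations follow a
## multivariate Student-t around per-individual locations, so gross
## outliers are downweighted through the tail-thickness parameter nu
## rather than distorting the correlation estimate. The correlation
## matrix is parametrized by its Cholesky factor in spherical coordinates
## (one angle per lower-triangular entry), which guarantees every
## posterior draw is symmetric with unit diagonal and positive definite
## in any dimension. Inputs are standardized per column before fitting;
## correlations are scale-invariant so results are unaffected.

## unrolled JAGS assignments for the spherical-Cholesky factor L (d known
## at model-build time; JAGS cannot express the degenerate index ranges)
chol_angle_lines <- function(d) {
  out <- "L[1,1] <- 1"
  if (d > 1) for (i in 2:d) {
    prods <- "1"
    for (j in 1:(i - 1)) {
      out <- c(out, sprintf("L[%d,%d] <- cos(theta[%d,%d]) * %s", i, j, i, j, prods))
      prods <- sprintf("%s * sin(theta[%d,%d])", prods, i, j)
    }
    out <- c(out, sprintf("L[%d,%d] <- %s", i, i, prods))
  }
  for (i in 1:d) for (j in seq_len(d)) if (j > i)
    out <- c(out, sprintf("L[%d,%d] <- 0", i, j))
  out
}

robust_cor_model <- function(d, hierarchical) {
  lik <- if (hierarchical) c(
    "for (i in 1:N) {",
    "  for (v in 1:D) { loc[i,v] <- mu[v] + a[id[i],v] }",
    "  y[i,1:D] ~ dmt(loc[i,1:D], Tau[1:D,1:D], nu)",
    "}",
    "for (j in 1:J) { for (v in 1:D) { a[j,v] ~ dnorm(0, tau_a[v]) } }",
    "for (v in 1:D) { sig_a[v] ~ dnorm(0, 1) T(0,) ; tau_a[v] <- pow(sig_a[v], -2) }"
  ) else
    "for (i in 1:N) { y[i,1:D] ~ dmt(mu[1:D], Tau[1:D,1:D], nu) }"
  paste(c("model {", lik, chol_angle_lines(d),
    "Rm <- L %*% t(L)",
    "for (i in 1:D) { for (j in 1:D) { Sig[i,j] <- sig[i] * sig[j] * Rm[i,j] } }",
    "Tau <- inverse(Sig)",
    "for (i in 2:D) { for (j in 1:(i-1)) { theta[i,j] ~ dunif(0.005, 3.136593) } }",
    "for (k in 1:D) { mu[k] ~ dnorm(0, 0.25) ; sig[k] ~ dnorm(0, 1) T(0,) }",
    "nu ~ dgamma(2, 0.1) T(2,)",
    "}"), collapse = "\n")
}

#' Hierarchical robust correlation under a multivariate Student-t
#'
#' Fits `y_ij ~ MVT(nu, mu + alpha_j, S)` with `S = diag(sigma) R
#' diag(sigma)`; the random intercepts `alpha_j` are variable-specific per
#' individual (omitted when `ids` is `NULL`). The degrees of freedom `nu`
#' get a Gamma(2, 0.1) prior truncated above 2, so small `nu` (heavy
#' tails) is available to absorb outliers while clean data push `nu` high,
#' recovering the Gaussian estimate.
#'
#' @param data data.frame or matrix of observations x variables (>= 2
#'   numeric columns); non-numeric columns are dropped, rows with missing
#'   values removed listwise.
#' @param ids optional individual labels (length `nrow(data)`) enabling
#'   the hierarchical random-intercept layer.
#' @param chains,iter,warmup,seed MCMC settings.
#' @return object of class `cor_fit`: `R_draws` (array draws x d x d),
#'   `draws` (monitored matrix incl. `sig`, `nu`), `variables`, `rhat`,
#'   `ess`, `converged`.
#' @export
fit_robust_correlation <- function(data, ids = NULL, chains = 4,
                                   iter = 1000, warmup = 500, seed = 1) {
  y <- as.data.frame(data)
  y <- y[vapply(y, is.numeric, logical(1))]
  if (ncol(y) < 2) stop_nutgeom("need >= 2 numeric variables")
  keep <- complete.cases(y)
  y <- y[keep, , drop = FALSE]
  sds <- vapply(y, sd, numeric(1))
  if (any(sds == 0))
    stop_nutgeom("constant column(s): ",
                 paste(names(y)[sds == 0], collapse = ", "))
  ys <- scale(y)
  d <- ncol(ys)
  dat <- list(y = unclass(ys), N = nrow(ys), D = d)
  hier <- !is.null(ids)
  if (hier) {
    f <- factor(ids[keep])
    if (nlevels(f) < 2) stop_nutgeom("need >= 2 individuals for hierarchy")
    dat$id <- as.integer(f)
    dat$J <- nlevels(f)
  }
  # JAGS infers theta's dims as (d, d-1) from the model's index ranges;
  # initialize declared angles at pi/2 (zero correlation)
  theta0 <- matrix(NA_real_, d, max(d - 1, 1))
  for (i in 2:d) theta0[i, seq_len(i - 1)] <- pi / 2
  ini <- list(mu = rep(0, d), sig = rep(1, d), nu = 20, theta = theta0)
  if (hier) ini$a <- matrix(0, dat$J, d)
  params <- c("Rm", "mu", "sig", "nu", if (hier) "sig_a")
  fit <- run_jags(robust_cor_model(d, hier), dat, params,
                  n_chains = chains, n_iter = iter, n_warmup = warmup,
                  seed = seed, inits = ini)
  rm_cols <- outer(seq_len(d), seq_len(d),
                   function(i, j) sprintf("Rm[%d,%d]", i, j))
  R_draws <- array(fit$draws[, as.vector(rm_cols)],
                   dim = c(nrow(fit$draws), d, d))
  dimnames(R_draws) <- list(NULL, colnames(y), colnames(y))
  structure(list(R_draws = R_draws, draws = fit$draws, mcmc = fit$mcmc,
                 variables = colnames(y), hierarchical = hier,
                 rhat = fit$rhat, ess = fit$ess, converged = fit$converged,
                 settings = fit[c("n_chains", "n_iter", "n_warmup", "seed")]),
            class = "cor_fit")
}

#' @export
print.cor_fit <- function(x, ...) {
  cat("<cor_fit>", length(x$variables), "variables,",
      dim(x$R_draws)[1], "draws,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(correlation_summary(x))
  invisible(x)
}

#' Summarize pairwise correlations from a robust-correlation fit
#'
#' @param fit a [fit_robust_correlation()] result.
#' @param level credible level of the central interval.
#' @return data.frame with one row per unordered variable pair:
#'   `var1`, `var2`, `mean`, `lwr`, `upr`, `p_gt0`.
#' @export
correlation_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "cor_fit"))
  d <- length(fit$variables)
  rows <- list()
  for (i in seq_len(d - 1)) for (j in (i + 1):d) {
    r <- fit$R_draws[, j, i]
    ci <- cred_int(r, level)
    rows[[length(rows) + 1]] <- data.frame(
      var1 = fit$variables[i], var2 = fit$variables[j],
      mean = mean(r), lwr = ci[1], upr = ci[2], p_gt0 = mean(r > 0))
  }
  do.call(rbind, rows)
}

#' Check positive definiteness of every posterior correlation draw
#' @param fit a `cor_fit`.
#' @return logical vector, one entry per draw.
#' @export
cor_draws_pd <- function(fit) {
  apply(fit$R_draws, 1, function(R)
    all(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 0))
}
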