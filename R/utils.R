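#' @importFrom stats rnorm runif rgamma rbinom rlnorm qnorm pnorm dnorm
#'   dlnorm dgamma dbinom plogis qlogis quantile var sd median
#'   complete.cases setNames uniroot model.matrix update
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic sub-stream seeds: one master integer seed, one stream per
## named stage. Kept below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 48271 + h * 1103) %% 2147483629)
}

## Normal draws truncated below (inverse-CDF method; exact, vectorized)
rnorm_lower <- function(n, mean, sd, lower) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

## Multivariate normal draws via Cholesky
rmvn <- function(n, mu, Sigma) {
  d <- length(mu)
  z <- matrix(rnorm(n * d), n, d) %*% chol(Sigma)
  sweep(z, 2, mu, "+")
}

## ---- MCMC plumbing -------------------------------------------------------

jags_chain_inits <- function(n_chains, seed, extra = NULL) {
  lapply(seq_len(n_chains), function(ch) {
    ini <- if (is.function(extra)) extra(ch) else (extra %||% list())
    ini$.RNG.name <- "base::Mersenne-Twister"
    ini$.RNG.seed <- derive_seed(seed, paste0("chain", ch))
    ini
  })
}

#' Run a JAGS model and collect draws with convergence diagnostics
#'
#' Thin wrapper around [rjags::jags.model()] / [rjags::coda.samples()] used by
#' every model-fitting function in the package. Draws are returned both as a
#' single matrix (all chains stacked) and as the underlying `mcmc.list`, with
#' split-Rhat and effective sample sizes attached.
#'
#' @param model_string JAGS model code.
#' @param data named list of data nodes.
#' @param params character vector of nodes to monitor.
#' @param n_chains,n_iter,n_warmup sampler settings; `n_iter` counts
#'   post-warmup iterations per chain.
#' @param seed integer master seed; per-chain RNG seeds are derived from it.
#' @param inits optional list of initial values (shared across chains) or a
#'   `function(chain)` returning one.
#' @param thin thinning interval.
#' @return list with elements `draws` (matrix, iterations x parameters),
#'   `mcmc` (coda `mcmc.list`), `rhat`, `ess`, `converged`
#'   (all Rhat < 1.01), and the sampler settings.
#' @keywords internal
run_jags <- function(model_string, data, params, n_chains = 4,
                     n_iter = 1000, n_warmup = 500, seed = 1,
                     inits = NULL, thin = 1) {
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  jm <- rjags::jags.model(con, data = data,
                          inits = jags_chain_inits(n_chains, seed, inits),
                          n.chains = n_chains, quiet = TRUE)
  if (n_warmup > 0) update(jm, n_warmup, progress.bar = "none")
  mc <- rjags::coda.samples(jm, variable.names = params, n.iter = n_iter,
                            thin = thin, progress.bar = "none")
  draws <- do.call(rbind, lapply(mc, as.matrix))
  rhat <- split_rhat(mc)
  ess <- tryCatch(coda::effectiveSize(mc), error = function(e) rep(NA_real_, ncol(draws)))
  list(draws = draws, mcmc = mc, rhat = rhat, ess = ess,
       converged = all(is.finite(rhat) & rhat < 1.01) || all(!is.finite(rhat)),
       n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup, seed = seed)
}

## Split-Rhat (potential scale reduction on split half-chains). Parameters
## with (numerically) zero variance across all chains get Rhat = 1.
split_rhat <- function(mc) {
  mats <- lapply(mc, as.matrix)
  p <- ncol(mats[[1]])
  out <- setNames(numeric(p), colnames(mats[[1]]))
  for (j in seq_len(p)) {
    halves <- unlist(lapply(mats, function(m) {
      x <- m[, j]
      n2 <- floor(length(x) / 2)
      list(x[seq_len(n2)], x[seq.int(length(x) - n2 + 1, length(x))])
    }), recursive = FALSE)
    n <- min(lengths(halves))
    ch <- vapply(halves, function(x) x[seq_len(n)], numeric(n))
    m_ch <- colMeans(ch)
    v_ch <- apply(ch, 2, var)
    W <- mean(v_ch)
    B <- n * var(m_ch)
    out[j] <- if (W < .Machine$double.eps * max(1, mean(abs(m_ch)))^2) 1
              else sqrt(((n - 1) / n * W + B / n) / W)
  }
  out
}

## ---- PSIS Pareto-k -------------------------------------------------------

## Generalized Pareto shape fit (Zhang & Stephens 2009 profile posterior
## mean), used for the PSIS-LOO overfitting diagnostic.
gpd_khat <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 5 || x[n] <= x[1]) return(NA_real_)
  m <- 30 + floor(sqrt(n))
  prior_b <- x[floor(n / 4 + 0.5)]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * prior_b)
  lik <- vapply(theta, function(t) {
    k <- -mean(log1p(-t * x))
    n * (log(t / k) + k - 1)
  }, numeric(1))
  w <- exp(lik - max(lik)); w <- w / sum(w)
  t_hat <- sum(theta * w)
  -mean(log1p(-t_hat * x))
}

#' Pointwise PSIS Pareto-k diagnostics from a pointwise log-likelihood matrix
#'
#' For each observation, fits a generalized Pareto distribution to the upper
#' tail of the importance ratios used by leave-one-out cross-validation and
#' returns the shape estimate k. Values above 0.7 indicate observations whose
#' LOO estimate is unreliable (a standard proxy for overfitting).
#'
#' @param loglik matrix of pointwise log-likelihood values, draws x
#'   observations.
#' @return numeric vector of Pareto-k values, one per observation.
#' @export
psis_khat <- function(loglik) {
  stopifnot(is.matrix(loglik))
  apply(loglik, 2, function(ll) {
    lr <- -ll                      # log importance ratios for LOO
    lr <- lr - max(lr)
    r <- exp(lr)
    ncut <- min(length(r) - 1, ceiling(min(0.2 * length(r), 3 * sqrt(length(r)))))
    tail_r <- sort(r, decreasing = TRUE)[seq_len(ncut)]
    cutoff <- min(tail_r)
    gpd_khat(tail_r - cutoff)
  })
}

## ---- misc ---------------------------------------------------------------

## central credible interval from draws
cred_int <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), names = FALSE))
}

month_key <- function(dates) format(as.Date(dates), "%Y-%m")

stop_nutgeom <- function(...) stop(..., call. = FALSE)
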