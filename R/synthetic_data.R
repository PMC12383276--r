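## Synthetic field-study generator: phenology plots, full-day follow
## macronutrient intakes, and urinary biomarkers with known ground truth.
##
## The defaults encode the study conditions the downstream analyses assume:
## a seasonal fruit availability index (FAI, percent of monitored trees
## fruiting, range 0.5-14%), saturating dependence of non-protein energy
## (NPe) intake on FAI with ~40% marginal CV, near-constant protein intake
## (~10.1% of calories, ~25% CV) linked to total energy by a power law with
## exponent L, per-individual random intercepts, and urinary biomarkers
## (C-peptide log-normal, urea gamma, d15N Gaussian, ketones Bernoulli)
## whose locations are smooth functions of the prior day's intake, diluted
## by specific gravity so that SG correction inverts the dilution exactly.

SCENARIOS <- c("complete_prioritization", "partial_prioritization",
               "no_prioritization", "flat_null")

#' Ground-truth parameters for the synthetic study
#'
#' Builds the full set of generating parameters for one simulation scenario.
#' Scenarios differ in the protein-prioritization exponent `l_true` of the
#' power law relating percent protein energy to total energy intake
#' (`complete_prioritization` fixes absolute protein intake, implying
#' `l_true = -1`; `no_prioritization` fixes the protein *proportion*,
#' implying `l_true = 0`; `partial_prioritization` defaults to
#' `l_true = -0.73`) and in whether the FAI and biomarker links are flat
#' (`flat_null`).
#'
#' @param scenario one of `"complete_prioritization"`,
#'   `"partial_prioritization"`, `"no_prioritization"`, `"flat_null"`.
#' @param seed integer master seed stored in the truth and used as the
#'   default seed of every `simulate_*` call.
#' @param l_true optional override of the generating exponent (only
#'   meaningful for `partial_prioritization`).
#' @return an object of class `sim_truth`: a list of generating parameters
#'   (see Details) including `l_true`, `a_protein` (protein energy share at
#'   the pivot energy), NPe-link parameters, per-biomarker link and family
#'   parameters, `rho_matrix`, `sd_individual`, `sg_mean = 1.023`, `sg_sd`,
#'   and ketone logit parameters.
#' @export
make_truth <- function(scenario, seed = 1L, l_true = NULL) {
  if (!is.character(scenario) || length(scenario) != 1L || !scenario %in% SCENARIOS)
    stop_nutgeom("unknown scenario ", deparse(scenario),
                 "; valid scenarios: ", paste(SCENARIOS, collapse = ", "))
  L <- switch(scenario,
    complete_prioritization = -1,
    partial_prioritization  = l_true %||% -0.73,
    no_prioritization       = 0,
    flat_null               = 0)
  if (scenario == "partial_prioritization" && (L <= -1 || L >= 0))
    stop_nutgeom("partial prioritization requires l_true strictly between -1 and 0")
  rho <- matrix(c(1.00, 0.75, 0.55, 0.30,
                  0.75, 1.00, 0.50, 0.25,
                  0.55, 0.50, 1.00, 0.35,
                  0.30, 0.25, 0.35, 1.00), 4, 4,
                dimnames = list(c("tnc", "lipid", "ndf", "protein"),
                                c("tnc", "lipid", "ndf", "protein")))
  stopifnot(isSymmetric(rho), all(eigen(rho, only.values = TRUE)$values > 0))
  truth <- list(
    scenario = scenario,
    seed = as.integer(seed),
    l_true = L,
    # protein share of total energy at the pivot energy e0 (study mean scale)
    a_protein = 0.104,
    e0 = 2525,                       # kcal/day pivot (mean total intake)
    # saturating NPe ~ FAI link: npe_lo + (npe_hi - npe_lo) * plogis((fai - fai_mid)/fai_scale)
    npe_lo = 1800, npe_hi = 2420, fai_mid = 4.56, fai_scale = 1.2,
    npe_sdlog = 0.385,               # ~40% marginal CV of daily NPe
    protein_sdlog = if (scenario == "complete_prioritization") 0.02 else 0.25,
    # split of NPe into components (logistic-normal jitter around these shares)
    npe_shares = c(tnc = 0.62, ndf = 0.27, lipid = 0.11),
    share_jitter_sd = 0.15,
    sd_individual = 0.10,            # random-intercept SD on log intake
                                     # and on log percent protein (the
                                     # power model's alpha)
    # per-individual random-intercept SDs on biomarker locations (link
    # scale; additive for d15N, log scale for concentrations and logit)
    bio_re = list(cpeptide = 0.08, urea = 0.08, d15n = 0.2, ketone = 0.3),
    # FAI seasonal generator
    fai_amp = 3.45, fai_ar_sd = 0.6, fai_ar_phi = 0.6,
    fai_spike_p = 0.015, fai_range = c(0.5, 14),
    # biomarker links (location as a function of prior-day intake, kcal)
    biomarker_links = list(
      cpeptide = list(base = log(1200), amp = 0, mid = 2200, scale = 500),
      urea     = list(base = 3.5, amp = 2.5, mid = 1500, scale = 450),
      d15n     = list(base = 6.5, amp = 1.2, mid = 800, scale = 250)),
    family_params = list(cpeptide_sdlog = 0.5, urea_shape = 6, d15n_sd = 0.5),
    # ketone positivity: logit linear in standardized TNC intake; steep so
    # positives concentrate on the lowest-carbohydrate days
    ketone_logit = list(b0 = -4.7, b1 = -3.5, tnc_mean = 1400, tnc_sd = 560),
    rho_matrix = rho,
    sg_mean = 1.023, sg_sd = 0.005)
  if (scenario == "flat_null") {
    truth$npe_hi <- truth$npe_lo     # flat FAI link
    for (b in names(truth$biomarker_links)) truth$biomarker_links[[b]]$amp <- 0
    truth$ketone_logit$b1 <- 0
    truth$ketone_logit$b0 <- qlogis(0.092)
  }
  class(truth) <- "sim_truth"
  truth
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", x$scenario, "\n",
      " l_true =", x$l_true, " a_protein =", x$a_protein,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Simulation design settings
#'
#' @param n_individuals number of focal individuals.
#' @param n_months number of phenology months.
#' @param trees_per_plot tagged trees monitored per month.
#' @param follows_per_individual full-day follows per individual.
#' @param urine_match_fraction fraction of full-day follows with a urine
#'   sample collected the following morning.
#' @param scenario scenario name (see [make_truth()]).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 40L, n_months = 84L,
                       trees_per_plot = 1600L, follows_per_individual = 40L,
                       urine_match_fraction = 0.5,
                       scenario = "partial_prioritization") {
  counts <- c(n_individuals, n_months, trees_per_plot, follows_per_individual)
  if (any(counts < 1)) stop_nutgeom("all design counts must be >= 1")
  if (urine_match_fraction < 0 || urine_match_fraction > 1)
    stop_nutgeom("urine_match_fraction must be in [0, 1]")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_months = as.integer(n_months),
                 trees_per_plot = as.integer(trees_per_plot),
                 follows_per_individual = as.integer(follows_per_individual),
                 urine_match_fraction = urine_match_fraction,
                 scenario = scenario),
            class = "sim_config")
}

## ---- link evaluators (parameters live in the truth; closures rebuilt
## here so the truth serializes to plain JSON) -----------------------------

#' Evaluate the ground-truth NPe vs FAI link
#' @param truth a `sim_truth`.
#' @param fai FAI values (percent, 0-100).
#' @return expected daily NPe intake (kcal) at each FAI; non-decreasing.
#' @export
eval_fai_link <- function(truth, fai) {
  truth$npe_lo + (truth$npe_hi - truth$npe_lo) *
    plogis((fai - truth$fai_mid) / truth$fai_scale)
}

#' Evaluate a ground-truth biomarker location link
#' @param truth a `sim_truth`.
#' @param biomarker `"cpeptide"`, `"urea"`, or `"d15n"`.
#' @param tnc prior-day TNC intake (kcal), the driving intake variable.
#' @return location parameter (meanlog for C-peptide, mean for urea and
#'   d15N) at each intake value.
#' @export
eval_biomarker_link <- function(truth, biomarker, tnc) {
  p <- truth$biomarker_links[[biomarker]]
  if (is.null(p)) stop_nutgeom("unknown biomarker ", biomarker)
  p$base + p$amp * (1 - plogis((tnc - p$mid) / p$scale))
}

#' Evaluate the ground-truth ketone-positivity logit
#' @param truth a `sim_truth`.
#' @param tnc prior-day TNC intake (kcal).
#' @return logit of the probability that a urine sample tests positive.
#' @export
eval_ketone_logit <- function(truth, tnc) {
  k <- truth$ketone_logit
  k$b0 + k$b1 * (tnc - k$tnc_mean) / k$tnc_sd
}

## monthly target FAI path: seasonal sinusoid + AR(1) + rare fruiting spikes
fai_path <- function(truth, n_months) {
  t <- seq_len(n_months)
  base <- truth$fai_mid + truth$fai_amp * sin(2 * pi * t / 12)
  e <- numeric(n_months)
  for (i in t) e[i] <- (if (i == 1) 0 else truth$fai_ar_phi * e[i - 1]) +
      rnorm(1, 0, truth$fai_ar_sd)
  spikes <- rbinom(n_months, 1, truth$fai_spike_p) * runif(n_months, 2, 6)
  pmin(pmax(base + e + spikes, truth$fai_range[1]), truth$fai_range[2])
}

#' Simulate monthly phenology-plot records
#'
#' One row per tagged tree per month with a fruiting flag. The implied
#' monthly FAI (percent of trees fruiting) follows a 12-month seasonal
#' cycle with autocorrelated noise and occasional high-fruit spikes,
#' clipped to the observed habitat range (0.5-14%); fruiting trees are
#' assigned so the realized FAI stays inside that range exactly.
#'
#' @param config a [sim_config()].
#' @param truth a [make_truth()] object.
#' @param seed integer seed (defaults to the truth's master seed).
#' @return data.frame with columns `tree_id`, `month` (`"YYYY-MM"`),
#'   `fruiting` (logical).
#' @export
simulate_phenology <- function(config, truth, seed = truth$seed) {
  set.seed(derive_seed(seed, "phenology"))
  months <- format(seq(as.Date("2010-01-01"), by = "month",
                       length.out = config$n_months), "%Y-%m")
  fai <- fai_path(truth, config$n_months)
  nt <- config$trees_per_plot
  lo_n <- ceiling(truth$fai_range[1] / 100 * nt)
  hi_n <- floor(truth$fai_range[2] / 100 * nt)
  out <- lapply(seq_along(months), function(m) {
    k <- min(max(round(fai[m] / 100 * nt), lo_n), hi_n)
    fr <- logical(nt)
    fr[sample.int(nt, k)] <- TRUE
    data.frame(tree_id = sprintf("T%04d", seq_len(nt)),
               month = months[m], fruiting = fr)
  })
  do.call(rbind, out)
}

## solve total energy E from NPe under the power law P = a*e0*(E/e0)^(1+L):
## E - NPe = P  =>  E - a*e0^( -L)*E^(1+L) = NPe (monotone in E)
solve_energy <- function(npe, a, e0, L) {
  if (L == -1) return(npe + a * e0)            # constant absolute protein
  if (L == 0) return(npe / (1 - a))            # constant proportion
  vapply(npe, function(np) {
    uniroot(function(E) E - a * e0 * (E / e0)^(1 + L) - np,
            lower = np, upper = np * 2 + 2 * a * e0, tol = 1e-8)$root
  }, numeric(1))
}

#' Simulate full-day follow macronutrient intakes
#'
#' Per individual-day kcal of protein, TNC, lipid and NDF. Expected NPe is
#' the truth's saturating function of that month's FAI with log-normal
#' noise and a per-individual random intercept; protein follows the
#' scenario's power law in total energy with its own multiplicative noise.
#'
#' @param config a [sim_config()].
#' @param truth a [make_truth()] object.
#' @param phenology table from [simulate_phenology()]; must cover the
#'   months of all generated follow dates.
#' @param seed integer seed.
#' @param partial_fraction fraction of follows flagged as partial days
#'   (`full_day = FALSE`), which downstream matching must exclude.
#' @return data.frame with columns `individual_id`, `date`, `sex`,
#'   `age_sex_class`, `kcal_protein`, `kcal_tnc`, `kcal_lipid`, `kcal_ndf`,
#'   `full_day`.
#' @export
simulate_follows <- function(config, truth, phenology, seed = truth$seed,
                             partial_fraction = 0.08) {
  set.seed(derive_seed(seed, "follows"))
  fai <- compute_fai(phenology)
  months <- fai$month
  d0 <- as.Date(paste0(months[1], "-01"))
  d1 <- seq(as.Date(paste0(months[length(months)], "-01")),
            by = "month", length.out = 2)[2] - 1
  all_days <- seq(d0, d1, by = "day")
  J <- config$n_individuals
  ids <- sprintf("ID%02d", seq_len(J))
  sexes <- rep(c("F", "M"), length.out = J)
  asc <- ifelse(sexes == "F", "adult_female",
                rep(c("flanged_male", "unflanged_male"), length.out = J))
  alpha <- rnorm(J, 0, truth$sd_individual)      # energy-level intercepts
  alpha_pp <- rnorm(J, 0, truth$sd_individual)   # %protein intercepts
  rows <- lapply(seq_len(J), function(j) {
    dates <- sort(sample(all_days, config$follows_per_individual))
    m <- month_key(dates)
    if (!all(m %in% months))
      stop_nutgeom("follow date outside phenology range")
    fai_d <- fai$fai[match(m, months)]
    mu_npe <- eval_fai_link(truth, fai_d)
    ## deterministic energy implied by the expected-NPe link, then
    ## log-normal day-to-day variation; percent protein then follows the
    ## scenario's power law in *observed* energy exactly, so the
    ## hierarchical log-log model downstream is correctly specified
    E_det <- solve_energy(mu_npe * exp(alpha[j]), truth$a_protein,
                          truth$e0, truth$l_true)
    E <- E_det * exp(rnorm(length(dates), 0, truth$npe_sdlog))
    pP <- truth$a_protein * (E / truth$e0)^truth$l_true *
      exp(alpha_pp[j] + rnorm(length(dates), 0, truth$protein_sdlog) -
            truth$protein_sdlog^2 / 2)
    prot <- pP * E
    npe <- E - prot
    # split NPe into components with logistic-normal jitter on the shares
    sh <- truth$npe_shares
    lsh <- matrix(log(sh), length(dates), 3, byrow = TRUE) +
      matrix(rnorm(3 * length(dates), 0, truth$share_jitter_sd), ncol = 3)
    sh_mat <- exp(lsh) / rowSums(exp(lsh))
    data.frame(individual_id = ids[j], date = as.character(dates),
               sex = sexes[j], age_sex_class = asc[j],
               kcal_protein = prot,
               kcal_tnc = npe * sh_mat[, 1],
               kcal_ndf = npe * sh_mat[, 2],
               kcal_lipid = npe * sh_mat[, 3],
               full_day = TRUE)
  })
  out <- do.call(rbind, rows)
  out$full_day <- runif(nrow(out)) >= partial_fraction
  rownames(out) <- NULL
  out
}

#' Simulate urinary biomarker samples from follow days
#'
#' Selects a fraction of full-day follows and generates one urine sample
#' dated the following day. C-peptide is log-normal, urea gamma, d15N
#' Gaussian, with locations given by the truth's links evaluated at the
#' prior day's TNC intake; ketone positivity is Bernoulli on the truth's
#' logit. True concentrations are diluted by `(sg - 1) / (sg_mean - 1)` so
#' that specific-gravity correction ([sg_correct()]) inverts the dilution
#' exactly; SG is drawn from a normal truncated above 1.000.
#'
#' @param follows table from [simulate_follows()].
#' @param truth a [make_truth()] object.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param orphan_fraction fraction of samples dated two days after their
#'   follow (so they have no prior-day follow and must be dropped by
#'   matching).
#' @param high_cv_fraction fraction of assay CVs drawn above the 15%
#'   quality threshold.
#' @return data.frame with columns `individual_id`, `collection_date`,
#'   `sg`, `cpeptide_pg_ml`, `urea_mg_ml`, `d15n_permil`,
#'   `ketone_category`, `cpeptide_cv`, `urea_cv`.
#' @export
simulate_urine <- function(follows, truth, config, seed = truth$seed,
                           orphan_fraction = 0.04, high_cv_fraction = 0.04) {
  if (nrow(follows) == 0) stop_nutgeom("follows table is empty")
  set.seed(derive_seed(seed, "urine"))
  full <- follows[follows$full_day, ]
  n_s <- round(nrow(full) * config$urine_match_fraction)
  sel <- full[sort(sample.int(nrow(full), n_s)), ]
  lag <- 1 + (runif(n_s) < orphan_fraction)     # 1 day, or 2 (orphan)
  sg <- rnorm_lower(n_s, truth$sg_mean, truth$sg_sd, 1.000)
  dil <- (sg - 1) / (truth$sg_mean - 1)
  tnc <- sel$kcal_tnc
  fp <- truth$family_params
  ## per-individual random intercepts on the biomarker locations (the
  ## maximal random-effect structure the downstream models assume)
  ids_f <- factor(sel$individual_id)
  re <- lapply(truth$bio_re, function(s)
    rnorm(nlevels(ids_f), 0, s)[as.integer(ids_f)])
  cp_true <- rlnorm(n_s, eval_biomarker_link(truth, "cpeptide", tnc) +
                      re$cpeptide, fp$cpeptide_sdlog)
  ur_mu <- eval_biomarker_link(truth, "urea", tnc) * exp(re$urea)
  ur_true <- rgamma(n_s, shape = fp$urea_shape, rate = fp$urea_shape / ur_mu)
  d15n <- rnorm(n_s, eval_biomarker_link(truth, "d15n", tnc) + re$d15n,
                fp$d15n_sd)
  pos <- runif(n_s) < plogis(eval_ketone_logit(truth, tnc) + re$ketone)
  cats <- ifelse(pos,
                 sample(c("trace", "+", "++", "+++"), n_s, replace = TRUE,
                        prob = c(0.5, 0.3, 0.15, 0.05)),
                 "negative")
  rcv <- function(n) ifelse(runif(n) < high_cv_fraction,
                            runif(n, 15.1, 25), runif(n, 2, 13))
  data.frame(individual_id = sel$individual_id,
             collection_date = as.character(as.Date(sel$date) + lag),
             sg = sg,
             cpeptide_pg_ml = cp_true * dil,
             urea_mg_ml = ur_true * dil,
             d15n_permil = d15n,                 # isotope ratio: not diluted
             ketone_category = cats,
             cpeptide_cv = rcv(n_s), urea_cv = rcv(n_s),
             row.names = NULL)
}

#' Simulate correlated log-intake observations from the truth's
#' correlation matrix
#'
#' Draws per-day log-scale intake deviations for the four macronutrients
#' from a multivariate normal with correlation `truth$rho_matrix`, plus
#' per-individual random intercepts. Used to validate the hierarchical
#' robust-correlation estimator against known ground truth.
#'
#' @param truth a `sim_truth`.
#' @param n_individuals,days_per_individual design size.
#' @param seed integer seed.
#' @param marginal_sd within-individual SD of each log-intake column.
#' @return data.frame with `individual_id` plus one column per intake
#'   variable (log kcal deviations).
#' @export
simulate_correlated_intakes <- function(truth, n_individuals = 20,
                                        days_per_individual = 25,
                                        seed = truth$seed,
                                        marginal_sd = 0.3) {
  set.seed(derive_seed(seed, "correlated"))
  d <- nrow(truth$rho_matrix)
  Sigma <- (marginal_sd^2) * truth$rho_matrix
  n <- n_individuals * days_per_individual
  id <- rep(seq_len(n_individuals), each = days_per_individual)
  alpha <- matrix(rnorm(n_individuals * d, 0, truth$sd_individual),
                  n_individuals, d)
  y <- rmvn(n, rep(0, d), Sigma) + alpha[id, ]
  colnames(y) <- rownames(truth$rho_matrix)
  cbind(data.frame(individual_id = sprintf("ID%02d", id)), as.data.frame(y))
}

## ---- persistence --------------------------------------------------------

#' Write the three simulated tables and the truth file to a directory
#' @param dir output directory (created if missing).
#' @param phenology,follows,urine simulated tables.
#' @param truth the `sim_truth` used.
#' @return invisibly, the paths written.
#' @export
write_sim_tables <- function(dir, phenology, follows, urine, truth) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("phenology.csv", "follows.csv", "urine.csv",
                            "truth.json"))
  write.csv(phenology, paths[1], row.names = FALSE)
  write.csv(follows, paths[2], row.names = FALSE)
  write.csv(urine, paths[3], row.names = FALSE)
  write_truth(truth, paths[4])
  invisible(paths)
}

#' Serialize / restore a `sim_truth` as JSON
#' @param truth a `sim_truth`.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$rho_matrix <- list(values = as.vector(x$rho_matrix),
                       names = rownames(x$rho_matrix))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(x$rho_matrix$names)
  x$rho_matrix <- matrix(x$rho_matrix$values, d, d,
                         dimnames = list(x$rho_matrix$names, x$rho_matrix$names))
  x$npe_shares <- unlist(x$npe_shares)
  class(x) <- "sim_truth"
  x
}
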