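## Cleaning, normalization, and prior-day matching of urinary biomarker
## samples: specific-gravity correction, dilute-sample exclusion, assay-CV
## filtering, ketone dichotomization, and the join to full-day intakes.

KETONE_LEVELS <- c("negative", "trace", "+", "++", "+++", "missing")

#' Specific-gravity correction of urinary analyte concentrations
#'
#' Corrects a concentration for hydration-driven dilution:
#' `corrected = value * (sg_ref - 1) / (sg - 1)`, where `sg_ref` is the
#' population mean specific gravity (1.023 for this population). Undefined
#' for `sg <= 1` (pure-water density), which is an error.
#'
#' @param value concentration(s) in the analyte's native units.
#' @param sg specific gravity of the sample(s).
#' @param sg_ref population reference SG.
#' @return corrected concentration(s).
#' @export
sg_correct <- function(value, sg, sg_ref = 1.023) {
  if (any(sg <= 1.000))
    stop_nutgeom("SG correction undefined for sg <= 1.000")
  value * (sg_ref - 1) / (sg - 1)
}

#' Exclude overly dilute urine samples
#'
#' Removes samples with specific gravity strictly below the threshold
#' (dilute samples yield exceedingly high SG-adjusted concentrations).
#'
#' @param samples urine-sample data.frame with an `sg` column.
#' @param threshold exclusion threshold; samples with `sg < threshold` are
#'   dropped, samples exactly at it retained.
#' @return list with `samples` (retained rows) and `log` (data.frame with
#'   the rule and the number of rows removed).
#' @export
exclude_dilute <- function(samples, threshold = 1.002) {
  drop <- samples$sg < threshold
  list(samples = samples[!drop, , drop = FALSE],
       log = data.frame(rule = sprintf("sg < %g", threshold),
                        n_excluded = sum(drop)))
}

#' Censor analyte values with unacceptable assay variation
#'
#' Sets the analyte's value to `NA` on samples whose assay coefficient of
#' variation exceeds the threshold (strictly; a CV exactly at the
#' threshold is retained). Other analytes are untouched and the row is
#' kept. Idempotent.
#'
#' @param samples urine-sample data.frame.
#' @param analyte value column name, e.g. `"cpeptide_pg_ml"`.
#' @param cv_col CV column name; defaults to the analyte's stem + `"_cv"`.
#' @param threshold CV threshold in percent.
#' @return the table with the analyte censored where CV > threshold.
#' @export
filter_cv <- function(samples, analyte, cv_col = NULL, threshold = 15) {
  cv_col <- cv_col %||% paste0(sub("_[^_]+_[^_]+$", "", analyte), "_cv")
  if (!cv_col %in% names(samples))
    stop_nutgeom("no CV column ", cv_col, " in samples")
  bad <- !is.na(samples[[cv_col]]) & samples[[cv_col]] > threshold
  samples[[analyte]][bad] <- NA
  samples
}

#' Dichotomize colorimetric ketone readings
#'
#' Maps the ordinal test-strip category to presence/absence. By default any
#' color change (including trace) counts as positive, maximizing
#' sensitivity given that the strips detect only acetoacetate and miss
#' mild ketosis; set `trace_positive = FALSE` to require at least `+`.
#'
#' @param category character vector with values among `"negative"`,
#'   `"trace"`, `"+"`, `"++"`, `"+++"`, `"missing"` (or `NA`).
#' @param trace_positive should `"trace"` count as positive?
#' @return logical vector (`NA` for missing readings).
#' @export
ketone_presence <- function(category, trace_positive = TRUE) {
  category[is.na(category)] <- "missing"
  bad <- setdiff(unique(category), KETONE_LEVELS)
  if (length(bad))
    stop_nutgeom("unknown ketone category: ", paste(bad, collapse = ", "))
  pos <- if (trace_positive) c("trace", "+", "++", "+++") else c("+", "++", "+++")
  out <- category %in% pos
  out[category == "missing"] <- NA
  out
}

#' Match urine samples to the prior day's full-day intake
#'
#' Joins each urine sample to the follow day dated exactly one day before
#' collection; samples whose prior day was not followed, or was not a full
#' nest-to-nest day, are dropped and counted. The month's FAI and fruit
#' period label are attached. SG correction of concentration analytes is
#' applied here (after dilute-sample exclusion), and ketone categories are
#' dichotomized.
#'
#' @param samples urine-sample data.frame (see [simulate_urine()] for the
#'   schema).
#' @param follows follow-day data.frame with derived intakes (see
#'   [add_derived_intakes()]; applied automatically if absent).
#' @param fai data.frame from [classify_fruit_periods()].
#' @param sg_ref reference SG passed to [sg_correct()].
#' @param conc_cols analyte columns subject to SG correction.
#' @param trace_positive passed to [ketone_presence()].
#' @return list with `matched` (one row per matched sample: corrected
#'   sample fields + prior-day intake fields + `fai`, `period_label`,
#'   `ketone_positive`) and `log` (exclusion counts per rule).
#' @export
match_urine_to_intake <- function(samples, follows, fai,
                                  sg_ref = 1.023,
                                  conc_cols = c("cpeptide_pg_ml", "urea_mg_ml"),
                                  trace_positive = TRUE) {
  if (!"period_label" %in% names(fai))
    stop_nutgeom("fai must carry period labels; run classify_fruit_periods()")
  if (!"kcal_total" %in% names(follows)) follows <- add_derived_intakes(follows)
  if (anyDuplicated(follows[c("individual_id", "date")]))
    stop_nutgeom("duplicate (individual_id, date) follow rows")
  dil <- exclude_dilute(samples)
  s <- dil$samples
  for (cc in intersect(conc_cols, names(s)))
    s[[cc]] <- sg_correct(s[[cc]], s$sg, sg_ref)
  prior <- as.character(as.Date(s$collection_date) - 1)
  idx <- match(paste(s$individual_id, prior),
               paste(follows$individual_id, follows$date))
  no_follow <- is.na(idx)
  partial <- !no_follow & !follows$full_day[idx]
  keep <- !no_follow & !partial
  matched <- cbind(s[keep, , drop = FALSE],
                   follows[idx[keep],
                           setdiff(names(follows), c("individual_id")),
                           drop = FALSE])
  names(matched)[names(matched) == "date"] <- "follow_date"
  fidx <- match(month_key(matched$follow_date), fai$month)
  matched$fai <- fai$fai[fidx]
  matched$period_label <- fai$period_label[fidx]
  matched$ketone_positive <- ketone_presence(matched$ketone_category,
                                             trace_positive = trace_positive)
  rownames(matched) <- NULL
  list(matched = matched,
       log = data.frame(
         rule = c(dil$log$rule, "no prior-day follow", "prior day not full"),
         n_excluded = c(dil$log$n_excluded, sum(no_follow), sum(partial))))
}
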