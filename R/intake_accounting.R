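## Fruit availability, fruit-period classification, and daily
## macronutrient/energy accounting for full-day feeding follows.

MACROS <- c("protein", "tnc", "lipid", "ndf")

#' Default kcal-per-gram conversion factors
#'
#' Metabolizable-energy conversion factors used when aggregating feeding
#' records: 4 kcal/g for protein and nonstructural carbohydrate, 9 kcal/g
#' for lipid, and 1.6 kcal/g for neutral detergent fiber (the fermentable
#' fiber convention for hindgut-fermenting herbivores). Overridable in
#' [compute_daily_intake()].
#' @export
kcal_factors_default <- c(protein = 4, tnc = 4, lipid = 9, ndf = 1.6)

#' Compute the monthly fruit availability index (FAI)
#'
#' FAI for a month is 100 times the number of fruiting trees divided by the
#' number of trees observed that month. Invariant to row order and tree
#' relabeling.
#'
#' @param phenology data.frame with columns `tree_id`, `month`, `fruiting`
#'   (logical or 0/1); one row per tree per month.
#' @return data.frame with columns `month` (sorted) and `fai` (percent,
#'   0-100).
#' @export
compute_fai <- function(phenology) {
  need <- c("tree_id", "month", "fruiting")
  if (!all(need %in% names(phenology)))
    stop_nutgeom("phenology needs columns ", paste(need, collapse = ", "))
  if (anyDuplicated(phenology[c("tree_id", "month")]))
    stop_nutgeom("duplicate (tree_id, month) phenology rows")
  months <- sort(unique(as.character(phenology$month)))
  n_obs <- tapply(phenology$tree_id, phenology$month, length)[months]
  empty <- months[is.na(n_obs) | n_obs == 0]
  if (length(empty))
    stop_nutgeom("months with zero observed trees: ",
                 paste(empty, collapse = ", "))
  n_fruit <- tapply(as.logical(phenology$fruiting), phenology$month,
                    function(x) sum(x, na.rm = TRUE))[months]
  data.frame(month = months, fai = 100 * as.numeric(n_fruit) / as.numeric(n_obs),
             row.names = NULL)
}

#' Label months as low- or high-fruit periods by the reference median
#'
#' Months with FAI strictly above the median FAI over the reference span
#' are labeled `"high"`, all others `"low"` (months exactly at the median
#' are assigned to the scarcity class, a deterministic tie rule).
#'
#' @param fai data.frame from [compute_fai()].
#' @param reference_span months over which the cutoff median is computed;
#'   defaults to all months present.
#' @return `fai` with added columns `period_label` and attribute
#'   `fai_median` (the cutoff).
#' @export
classify_fruit_periods <- function(fai, reference_span = fai$month) {
  if (length(reference_span) == 0) stop_nutgeom("empty reference span")
  ref <- fai$fai[fai$month %in% reference_span]
  if (length(ref) == 0) stop_nutgeom("reference span matches no months")
  cut <- median(ref)
  fai$period_label <- ifelse(fai$fai > cut, "high", "low")
  attr(fai, "fai_median") <- cut
  fai
}

#' Aggregate feeding records into daily macronutrient intakes (kcal)
#'
#' For every feeding record, kcal of each macronutrient is
#' `dry mass (g) x dry-matter fraction x kcal/g factor`, summed within
#' individual-days. Days appear only if they have at least one record,
#' unless explicitly registered through `days` (which yields all-zero rows
#' for recordless registered days).
#'
#' @param records data.frame with columns `individual_id`, `date`,
#'   `food_item_id`, `units` (g dry matter), and optionally `full_day`.
#' @param compositions data.frame with columns `food_item_id`,
#'   `frac_protein`, `frac_tnc`, `frac_lipid`, `frac_ndf` (dry-matter
#'   fractions in [0,1]).
#' @param kcal_factors named kcal/g conversion factors; see
#'   [kcal_factors_default].
#' @param days optional data.frame (`individual_id`, `date`, optionally
#'   `full_day`) registering follow days, including zero-intake ones.
#' @return data.frame with one row per individual-date:
#'   `individual_id`, `date`, `kcal_protein`, `kcal_tnc`, `kcal_lipid`,
#'   `kcal_ndf`, `full_day`.
#' @export
compute_daily_intake <- function(records, compositions,
                                 kcal_factors = kcal_factors_default,
                                 days = NULL) {
  stopifnot(all(MACROS %in% names(kcal_factors)))
  if (any(records$units < 0)) stop_nutgeom("negative units in feeding records")
  idx <- match(records$food_item_id, compositions$food_item_id)
  if (anyNA(idx))
    stop_nutgeom("unknown food item(s): ",
                 paste(unique(records$food_item_id[is.na(idx)]), collapse = ", "))
  fr <- compositions[idx, paste0("frac_", MACROS), drop = FALSE]
  if (any(fr < 0 | fr > 1)) stop_nutgeom("dry-matter fractions must be in [0,1]")
  kc <- as.data.frame(Map(function(f, k) records$units * f * k,
                          fr, kcal_factors[MACROS]))
  names(kc) <- paste0("kcal_", MACROS)
  key <- interaction(records$individual_id, records$date, drop = TRUE)
  agg <- rowsum(kc, key)
  first <- !duplicated(key)
  out <- data.frame(individual_id = records$individual_id[first],
                    date = records$date[first])
  out <- cbind(out, agg[match(interaction(out$individual_id, out$date,
                                          drop = TRUE), rownames(agg)), ])
  out$full_day <- if ("full_day" %in% names(records))
    as.logical(tapply(records$full_day, key, all)[rownames(agg)][
      match(interaction(out$individual_id, out$date, drop = TRUE), rownames(agg))])
  else TRUE
  if (!is.null(days)) {
    k_out <- paste(out$individual_id, out$date)
    k_reg <- paste(days$individual_id, days$date)
    miss <- days[!(k_reg %in% k_out), , drop = FALSE]
    if (nrow(miss)) {
      zero <- data.frame(individual_id = miss$individual_id, date = miss$date,
                         kcal_protein = 0, kcal_tnc = 0, kcal_lipid = 0,
                         kcal_ndf = 0,
                         full_day = if ("full_day" %in% names(miss))
                           miss$full_day else TRUE)
      out <- rbind(out, zero)
    }
    if ("full_day" %in% names(days)) {
      m <- match(paste(out$individual_id, out$date), k_reg)
      out$full_day[!is.na(m)] <- days$full_day[m[!is.na(m)]]
    }
  }
  out <- out[order(out$individual_id, out$date), ]
  rownames(out) <- NULL
  out
}

#' Non-protein energy of follow days
#'
#' NPe is the sum of kcal from nonstructural carbohydrate, neutral
#' detergent fiber, and lipid.
#'
#' @param day data.frame of follow days with `kcal_tnc`, `kcal_ndf`,
#'   `kcal_lipid` columns.
#' @return numeric vector of NPe (kcal), one per row.
#' @export
compute_npe <- function(day) {
  day$kcal_tnc + day$kcal_ndf + day$kcal_lipid
}

#' Daily macronutrient intake ratio
#'
#' Sum of kcal over the numerator macronutrients divided by the sum over
#' the denominator macronutrients. Days with a zero denominator yield `NA`
#' (with a warning), never infinity.
#'
#' @param day data.frame of follow days.
#' @param numerator,denominator character vectors drawn from
#'   `"protein"`, `"tnc"`, `"lipid"`, `"ndf"`, `"npe"`.
#' @return numeric vector of ratios, one per row.
#' @export
compute_ratio <- function(day, numerator, denominator) {
  part <- function(set) {
    set <- match.arg(set, c(MACROS, "npe"), several.ok = TRUE)
    cols <- unique(unlist(lapply(set, function(s)
      if (s == "npe") c("kcal_tnc", "kcal_ndf", "kcal_lipid")
      else paste0("kcal_", s))))
    rowSums(day[, cols, drop = FALSE])
  }
  num <- part(numerator)
  den <- part(denominator)
  if (any(den == 0)) {
    warning("zero denominator kcal on ", sum(den == 0),
            " day(s); ratio set to NA", call. = FALSE)
    den[den == 0] <- NA_real_
  }
  num / den
}

#' Add derived energy columns to a follow-day table
#'
#' Adds `kcal_npe`, `kcal_total` (= protein + NPe), `pct_protein`
#' (percent of total energy from protein), and `npe_p` (NPe:protein
#' ratio).
#'
#' @param follows follow-day data.frame.
#' @return the table with derived columns appended.
#' @export
add_derived_intakes <- function(follows) {
  follows$kcal_npe <- compute_npe(follows)
  follows$kcal_total <- follows$kcal_protein + follows$kcal_npe
  follows$pct_protein <- 100 * follows$kcal_protein / follows$kcal_total
  follows$npe_p <- suppressWarnings(
    compute_ratio(follows, "npe", "protein"))
  follows
}
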