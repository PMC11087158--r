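#' @title Headroom-based clinical significance
#' @description A dose change matters clinically in proportion to how close
#'   the organ already is to its tolerance. The dosimetric headroom is
#'   tolerance minus the gold-standard metric dose; per organ and protocol,
#'   half of the cohort-average headroom (first-order organs) or half of the
#'   worst-case (minimum) headroom (second-order mean-dose-like organs) is
#'   used as the clinical-significance threshold. A case is flagged when its
#'   gold-vs-auto dose change exceeds the threshold in either direction.
#'   Organs whose computed threshold would be non-positive, and second-order
#'   "other" organs (lenses, lacrimal glands, pituitary), are excluded from
#'   threshold classification and compared descriptively instead.
#' @name clinical_significance
NULL

#' Dosimetric headroom
#'
#' @param gold_dose gold-standard metric dose, cGy.
#' @param tolerance tolerance dose, cGy (> 0).
#' @return tolerance - gold_dose, cGy (may be negative).
#' @export
headroom <- function(gold_dose, tolerance) {
  if (any(tolerance <= 0)) stop("tolerance must be > 0")
  tolerance - gold_dose
}

#' Compute a clinical-significance threshold
#'
#' Average mode: `0.5 * mean(headrooms)`. Worst-case mode:
#' `0.5 * min(headrooms)` (the case with the least headroom to tolerance). A
#' non-positive result excludes the organ with reason `"negative headroom"`.
#'
#' @param gold_doses gold metric doses, cGy, for one organ under one
#'   protocol (>= 1 value; gold contours exist even for cases whose
#'   autosegmentation failed, so all cases contribute).
#' @param tolerance tolerance dose, cGy.
#' @param mode `"average_headroom"` or `"worst_case_headroom"`.
#' @return list of class `significance_threshold`: threshold_cGy, mode,
#'   n_cases_used, excluded, excluded_reason.
#' @export
compute_threshold <- function(gold_doses, tolerance,
                              mode = c("average_headroom",
                                       "worst_case_headroom")) {
  mode <- match.arg(mode)
  gold_doses <- as.numeric(gold_doses)
  if (!length(gold_doses) || anyNA(gold_doses))
    stop("at least one finite gold dose is required")
  hr <- headroom(gold_doses, tolerance)
  thr <- 0.5 * switch(mode, average_headroom = mean(hr),
                      worst_case_headroom = min(hr))
  excluded <- thr <= 0
  structure(list(threshold_cGy = thr, mode = mode,
                 n_cases_used = length(gold_doses),
                 excluded = excluded,
                 excluded_reason = if (excluded) "negative headroom"
                                   else NA_character_),
            class = "significance_threshold")
}

#' Route an organ tier to a threshold mode
#'
#' First-order organs (hard limits, near-maximal statistics) use the average
#' headroom; second-order mean-dose-like organs (cochlea D50%) use the
#' worst-case headroom; the remaining second-order organs are excluded from
#' threshold classification (descriptive model comparison only).
#'
#' @param tier one of `"first_order"`, `"second_order_mean_like"`,
#'   `"second_order_other"` (an `oar_spec` row also works).
#' @return `"average_headroom"`, `"worst_case_headroom"` or `"excluded"`.
#' @export
tier_route <- function(tier) {
  if (is.data.frame(tier)) tier <- tier$tier
  if (length(tier) != 1L ||
      !tier %in% c("first_order", "second_order_mean_like",
                   "second_order_other"))
    stop("unknown significance tier: ", paste(tier, collapse = ", "))
  switch(tier,
         first_order = "average_headroom",
         second_order_mean_like = "worst_case_headroom",
         second_order_other = "excluded")
}

#' Classify one case against a threshold
#'
#' Flagged iff `|delta_cGy|` strictly exceeds the threshold ("more than half
#' the headroom, in either direction"); ties are not flagged.
#'
#' @param delta_cGy signed dose change, cGy (scalar; `NA` for failed cases).
#' @param threshold a [compute_threshold()] result.
#' @return logical flag, or `NA` when the delta is unavailable.
#' @export
classify_case <- function(delta_cGy, threshold) {
  stopifnot(inherits(threshold, "significance_threshold"))
  if (threshold$excluded)
    stop("classification unavailable: organ excluded (",
         threshold$excluded_reason, ")")
  ifelse(is.na(delta_cGy), NA, abs(delta_cGy) > threshold$threshold_cGy)
}

#' Cohort clinical-significance report
#'
#' Per organ x protocol, derives the threshold from the gold doses of all
#' cases under that protocol (mode routed by tier), then flags each model's
#' cases. Tier-excluded and negative-headroom organs are carried in the
#' report with their exclusion reason and no flags. Protocols are never
#' pooled.
#'
#' @param per_case per-case metric table ([evaluate_cohort()] output):
#'   columns case_id, protocol, model, organ, gold_cGy, delta_cGy, status.
#' @param oar_table constraint table, default [default_oar_table()].
#' @param mean_like_rule for worst-case-mode organs, `"T"` flags
#'   `|delta| > threshold` (default); `"T/2"` flags `|delta| > threshold/2`
#'   (the stricter reading of "more than half of this threshold").
#' @return data.frame: organ, protocol, model, mode, threshold_cGy,
#'   n_cases_used, n_flagged, flagged_case_ids (comma-joined),
#'   mean_abs_flagged_delta_cGy, mean_signed_flagged_delta_cGy,
#'   excluded_reason.
#' @export
significance_report <- function(per_case, oar_table = default_oar_table(),
                                mean_like_rule = c("T", "T/2")) {
  mean_like_rule <- match.arg(mean_like_rule)
  needed <- c("case_id", "protocol", "model", "organ", "gold_cGy",
              "delta_cGy", "status")
  if (!all(needed %in% names(per_case)))
    stop("per_case table lacks columns: ",
         paste(setdiff(needed, names(per_case)), collapse = ", "))
  rows <- list()
  for (organ in unique(per_case$organ)) {
    spec <- oar_table[oar_table$organ == organ, ]
    if (!nrow(spec)) stop("organ missing from constraint table: ", organ)
    mode <- tier_route(spec$tier)
    for (proto in sort(unique(per_case$protocol))) {
      sub <- per_case[per_case$organ == organ & per_case$protocol == proto, ]
      if (!nrow(sub)) next
      # gold doses: one per case (gold contours always exist)
      gold <- sub[!duplicated(sub$case_id), "gold_cGy"]
      thr_obj <- if (mode == "excluded") NULL
        else compute_threshold(gold, spec$tolerance_cGy, mode)
      excluded_reason <- if (mode == "excluded") "tier-excluded"
        else if (thr_obj$excluded) thr_obj$excluded_reason
        else NA_character_
      for (model in sort(unique(sub$model))) {
        ms <- sub[sub$model == model, ]
        if (!is.na(excluded_reason)) {
          rows[[length(rows) + 1L]] <- data.frame(
            organ = organ, protocol = proto, model = model,
            mode = mode, threshold_cGy = if (mode == "excluded") NA_real_
                                         else thr_obj$threshold_cGy,
            n_cases_used = length(gold), n_flagged = NA_integer_,
            flagged_case_ids = NA_character_,
            mean_abs_flagged_delta_cGy = NA_real_,
            mean_signed_flagged_delta_cGy = NA_real_,
            excluded_reason = excluded_reason, stringsAsFactors = FALSE)
          next
        }
        eff_thr <- thr_obj
        if (mode == "worst_case_headroom" && mean_like_rule == "T/2")
          eff_thr$threshold_cGy <- thr_obj$threshold_cGy / 2
        flags <- classify_case(ms$delta_cGy, eff_thr)
        flagged <- ms[!is.na(flags) & flags, ]
        rows[[length(rows) + 1L]] <- data.frame(
          organ = organ, protocol = proto, model = model, mode = mode,
          threshold_cGy = thr_obj$threshold_cGy,
          n_cases_used = length(gold), n_flagged = nrow(flagged),
          flagged_case_ids = if (nrow(flagged))
            paste(flagged$case_id, collapse = ",") else "",
          mean_abs_flagged_delta_cGy = if (nrow(flagged))
            mean(abs(flagged$delta_cGy)) else NA_real_,
          mean_signed_flagged_delta_cGy = if (nrow(flagged))
            mean(flagged$delta_cGy) else NA_real_,
          excluded_reason = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
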