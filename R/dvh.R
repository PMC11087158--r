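#' @title DVH dose statistics
#' @description The clinically reported organ-at-risk statistics: D1%, D5%
#'   and D50% are the minimum dose received by the most exposed 1%, 5% or 50%
#'   of the structure volume; Dmax is the single hottest voxel. D_x% follows
#'   the discrete rule "dose of the voxel at which the cumulative
#'   hottest-voxel volume first reaches x% of the structure volume" (no
#'   sub-voxel DVH interpolation), i.e. the ceiling(x/100 * n)-th value of the
#'   descending dose sort over the n mask voxels. Tie order cannot change the
#'   result.
#' @name dvh
NULL

.metric_kinds <- c("D1%", "D5%", "D50%", "Dmax")

#' Supported DVH metric kinds
#' @return character vector `c("D1%", "D5%", "D50%", "Dmax")`.
#' @export
metric_kinds <- function() .metric_kinds

#' Compute a DVH dose statistic over a structure
#'
#' @param dose a [dose_grid()].
#' @param mask a present, non-empty [structure_mask()] on a compatible grid.
#' @param metric one of [metric_kinds()].
#' @return dose in cGy (scalar). A failed or empty mask raises a
#'   "metric unavailable" error rather than returning 0.
#' @export
dose_metric <- function(dose, mask, metric = c("D1%", "D5%", "D50%", "Dmax")) {
  metric <- match.arg(metric)
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!mask$present || !any(mask$values))
    stop("metric unavailable: mask is ", mask$status)
  if (!grids_compatible(dose, mask))
    stop("dose grid and structure mask are on incompatible grids")
  doses <- dose$values[mask$values]
  if (metric == "Dmax") return(max(doses))
  x <- switch(metric, `D1%` = 1, `D5%` = 5, `D50%` = 50)
  k <- ceiling(x / 100 * length(doses))
  sort(doses, decreasing = TRUE)[max(k, 1L)]
}

#' Cumulative dose-volume histogram
#'
#' @param dose a [dose_grid()].
#' @param mask a present [structure_mask()].
#' @param edges dose edges, cGy; default 101 even steps from 0 to the mask
#'   maximum.
#' @return data.frame with `dose_cGy` and `volume_fraction` (fraction of the
#'   structure receiving at least each edge dose; starts at 1 at dose 0,
#'   monotone non-increasing).
#' @export
dvh_curve <- function(dose, mask, edges = NULL) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (!mask$present) stop("DVH unavailable: mask is ", mask$status)
  if (!grids_compatible(dose, mask)) stop("incompatible grids")
  doses <- dose$values[mask$values]
  if (is.null(edges)) edges <- seq(0, max(doses), length.out = 101)
  frac <- vapply(edges, function(e) mean(doses >= e), numeric(1))
  data.frame(dose_cGy = edges, volume_fraction = frac)
}

#' Organ-at-risk specification
#'
#' @param name organ name.
#' @param tolerance tolerance dose, cGy (> 0).
#' @param metric the organ's clinical DVH statistic, one of [metric_kinds()].
#' @param tier significance tier: `"first_order"` (hard planning limits,
#'   near-maximal statistics), `"second_order_mean_like"` (optimal tolerances
#'   with mean-dose-like statistics) or `"second_order_other"` (descriptive
#'   comparison only).
#' @return one-row data.frame of class `oar_spec`.
#' @export
oar_spec <- function(name, tolerance, metric, tier) {
  metric <- match.arg(metric, .metric_kinds)
  tier <- match.arg(tier, c("first_order", "second_order_mean_like",
                            "second_order_other"))
  if (tolerance <= 0) stop("tolerance must be > 0 cGy")
  df <- data.frame(organ = name, tolerance_cGy = as.numeric(tolerance),
                   metric = metric, tier = tier, stringsAsFactors = FALSE)
  class(df) <- c("oar_spec", "data.frame")
  df
}

#' Default organ-at-risk constraint table
#'
#' The glioma radical-primary VMAT constraint set (tolerances in cGy, one row
#' per lateralized organ, 13 rows): brainstem 5400 D5%; lenses 600 D1%; optic
#' chiasm 5400 D1%; optic nerves 5400 D1%; orbits 4500 D1%; lacrimal glands
#' 3000 D1%; pituitary 4500 Dmax; cochleae 4500 D50%. Tier assignment:
#' brainstem, orbits, chiasm and optic nerves are first-order; cochleae are
#' second-order mean-dose-like; lenses, lacrimal glands and pituitary are
#' second-order other (excluded from threshold classification).
#'
#' @return data.frame with columns organ, tolerance_cGy, metric, tier.
#' @export
default_oar_table <- function() {
  rows <- list(
    oar_spec("brainstem",     5400, "D5%",  "first_order"),
    oar_spec("optic_chiasm",  5400, "D1%",  "first_order"),
    oar_spec("optic_nerve_l", 5400, "D1%",  "first_order"),
    oar_spec("optic_nerve_r", 5400, "D1%",  "first_order"),
    oar_spec("orbit_l",       4500, "D1%",  "first_order"),
    oar_spec("orbit_r",       4500, "D1%",  "first_order"),
    oar_spec("lens_l",         600, "D1%",  "second_order_other"),
    oar_spec("lens_r",         600, "D1%",  "second_order_other"),
    oar_spec("lacrimal_l",    3000, "D1%",  "second_order_other"),
    oar_spec("lacrimal_r",    3000, "D1%",  "second_order_other"),
    oar_spec("pituitary",     4500, "Dmax", "second_order_other"),
    oar_spec("cochlea_l",     4500, "D50%", "second_order_mean_like"),
    oar_spec("cochlea_r",     4500, "D50%", "second_order_mean_like")
  )
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Gold-vs-auto dose delta for one structure
#'
#' Computes the organ's DVH statistic on the same dose grid for the
#' gold-standard and the autosegmented mask and reports the signed change.
#' Percent change is relative to the gold metric by default; pass
#' `percent_ref` to normalize by e.g. the prescription dose instead. A gold
#' metric of 0 leaves the percent undefined (status `"undefined-percent"`)
#' while the absolute delta is still reported. A failed (or eroded-away) auto
#' mask yields an unavailable delta with the mask's status, feeding the
#' cohort failure tally N*.
#'
#' @param dose a [dose_grid()].
#' @param gold present gold-standard [structure_mask()].
#' @param auto auto [structure_mask()] (may be failed).
#' @param metric one of [metric_kinds()].
#' @param percent_ref optional denominator (cGy) for percent change;
#'   default the gold metric value.
#' @return one-row data.frame: gold_cGy, auto_cGy, delta_cGy, percent,
#'   abs_percent, status (`ok`, `failed`, `eroded-away`,
#'   `undefined-percent`).
#' @export
dose_delta <- function(dose, gold, auto, metric, percent_ref = NULL) {
  stopifnot(inherits(gold, "structure_mask"), inherits(auto, "structure_mask"))
  if (!gold$present) stop("gold mask must be present")
  if (!grids_compatible(dose, gold)) stop("incompatible grids (dose vs gold)")
  gold_cGy <- dose_metric(dose, gold, metric)
  if (!auto$present) {
    return(data.frame(gold_cGy = gold_cGy, auto_cGy = NA_real_,
                      delta_cGy = NA_real_, percent = NA_real_,
                      abs_percent = NA_real_, status = auto$status,
                      stringsAsFactors = FALSE))
  }
  if (!grids_compatible(dose, auto)) stop("incompatible grids (dose vs auto)")
  auto_cGy <- dose_metric(dose, auto, metric)
  delta <- auto_cGy - gold_cGy
  ref <- if (is.null(percent_ref)) gold_cGy else as.numeric(percent_ref)
  if (ref == 0) {
    data.frame(gold_cGy = gold_cGy, auto_cGy = auto_cGy, delta_cGy = delta,
               percent = NA_real_, abs_percent = NA_real_,
               status = "undefined-percent", stringsAsFactors = FALSE)
  } else {
    pct <- 100 * delta / ref
    data.frame(gold_cGy = gold_cGy, auto_cGy = auto_cGy, delta_cGy = delta,
               percent = pct, abs_percent = abs(pct), status = "ok",
               stringsAsFactors = FALSE)
  }
}
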