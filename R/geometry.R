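#' @title Geometric agreement metrics
#' @description Dice similarity coefficient, sensitivity and mean
#'   distance-to-agreement between a gold-standard and an autosegmented mask.
#'   Failed segmentations carry no geometry (they are not Dice 0): the failed
#'   category is preserved separately downstream.
#' @name geometry
NULL

.check_geom_pair <- function(gold, auto) {
  stopifnot(inherits(gold, "structure_mask"), inherits(auto, "structure_mask"))
  if (!gold$present || !any(gold$values))
    stop("gold mask must be present and non-empty")
  if (!grids_compatible(gold, auto)) stop("incompatible grids")
}

#' Dice similarity coefficient
#'
#' `2|G n A| / (|G| + |A|)`. Symmetric; 1 iff the masks are identical,
#' 0 for disjoint (e.g. mislocated) masks. A failed auto mask returns `NA`.
#'
#' @param gold,auto [structure_mask()]s on compatible grids.
#' @return unitless in `[0, 1]`, or `NA` for failed auto.
#' @export
dsc <- function(gold, auto) {
  .check_geom_pair(gold, auto)
  if (!auto$present) return(NA_real_)
  g <- gold$values; a <- auto$values
  2 * sum(g & a) / (sum(g) + sum(a))
}

#' Sensitivity (gold-voxel recovery fraction)
#'
#' `|G n A| / |G|`. Not symmetric: a superset auto mask scores 1.
#'
#' @inheritParams dsc
#' @return unitless in `[0, 1]`, or `NA` for failed auto.
#' @export
sensitivity <- function(gold, auto) {
  .check_geom_pair(gold, auto)
  if (!auto$present) return(NA_real_)
  sum(gold$values & auto$values) / sum(gold$values)
}

# surface voxels: occupied voxels with >= 1 face-adjacent unoccupied neighbor
# (the grid boundary counts as unoccupied); mm coordinates of voxel centers
.surface_mm <- function(mask) {
  v <- mask$values
  interior <- array(TRUE, dim(v))
  n <- dim(v)
  for (ax in 1:3) for (sgn in c(-1L, 1L)) {
    dv <- c(0L, 0L, 0L); dv[ax] <- sgn
    interior <- interior & .shift_mask(v, dv[1], dv[2], dv[3])
  }
  surf <- v & !interior
  ind <- which(surf, arr.ind = TRUE)
  if (!nrow(ind)) stop("mask has no surface voxels")
  sweep(sweep(ind - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# for each row of a (n x 3 mm), distance to the nearest row of b (m x 3 mm)
.nn_dist <- function(a, b, chunk = 512L) {
  b2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  for (s in seq(1, nrow(a), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(a))
    ach <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(ach^2), b2, "+") - 2 * tcrossprod(ach, b)
    out[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Mean distance-to-agreement (symmetric mean surface distance)
#'
#' Surface voxels are occupied voxels with at least one face-adjacent
#' unoccupied neighbor (outside the grid counts as unoccupied). For every
#' surface voxel of each mask, the distance (mm, anisotropy-aware, between
#' voxel centers) to the nearest surface voxel of the other mask is taken;
#' the MDA is the mean over both directed distance sets pooled.
#'
#' @inheritParams dsc
#' @return mm >= 0, or `NA` for failed auto.
#' @export
mean_dta <- function(gold, auto) {
  .check_geom_pair(gold, auto)
  if (!auto$present) return(NA_real_)
  if (!any(auto$values)) stop("auto mask is empty but marked present")
  sg <- .surface_mm(gold)
  sa <- .surface_mm(auto)
  d_ag <- .nn_dist(sa, sg)
  d_ga <- .nn_dist(sg, sa)
  (sum(d_ag) + sum(d_ga)) / (length(d_ag) + length(d_ga))
}

#' All geometric agreement metrics for one structure pair
#'
#' @inheritParams dsc
#' @return one-row data.frame: dsc, sensitivity, mean_dta_mm, status.
#' @export
geometry_metrics <- function(gold, auto) {
  .check_geom_pair(gold, auto)
  if (!auto$present) {
    return(data.frame(dsc = NA_real_, sensitivity = NA_real_,
                      mean_dta_mm = NA_real_, status = auto$status,
                      stringsAsFactors = FALSE))
  }
  data.frame(dsc = dsc(gold, auto), sensitivity = sensitivity(gold, auto),
             mean_dta_mm = mean_dta(gold, auto), status = "ok",
             stringsAsFactors = FALSE)
}
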