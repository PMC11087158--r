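#' Autosegmentation error specification
#'
#' The error taxonomy mirrors failure modes observed when deep-learning
#' autosegmentation is audited against gold-standard contours:
#' \describe{
#'   \item{none}{identity; the model reproduced the contour.}
#'   \item{dilate / erode}{systematic over/under-segmentation, morphological
#'     ball of radius `magnitude` mm.}
#'   \item{translate}{rigid offset; `magnitude` is a length-3 mm displacement
#'     vector (z, y, x), applied as the nearest integer-voxel shift.}
#'   \item{truncate}{missing extent (e.g. an unidentified posterior limit):
#'     the last `magnitude` occupied slices along `axis` are removed.}
#'   \item{mislocate}{gross mislocation: the structure is moved so that it is
#'     disjoint from the gold contour (Dice 0) with voxel count preserved.}
#'   \item{fail}{the model produced no structure at all.}
#' }
#'
#' @param kind error kind, see Details.
#' @param magnitude mm (dilate/erode), mm vector (translate) or slice count
#'   (truncate); ignored for mislocate/fail.
#' @param axis truncation axis, `"z"`, `"y"` or `"x"`.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind = c("none", "dilate", "erode", "translate",
                                       "truncate", "mislocate", "fail"),
                              magnitude = 0, axis = "z") {
  kind <- match.arg(kind)
  axis <- match.arg(axis, c("z", "y", "x"))
  magnitude <- as.numeric(magnitude)
  if (kind == "translate") {
    if (length(magnitude) != 3L) stop("translate magnitude must be a length-3 mm vector")
  } else if (length(magnitude) != 1L || magnitude < 0) {
    stop("magnitude must be a single value >= 0")
  }
  structure(list(kind = kind, magnitude = magnitude, axis = axis),
            class = "perturbation_spec")
}

# integer-voxel shift of a logical array; voxels shifted outside are dropped
.shift_mask <- function(v, dz, dy, dx) {
  out <- array(FALSE, dim(v))
  n <- dim(v)
  src <- function(d, k) {
    lo <- max(1, 1 - d); hi <- min(k, k - d)
    if (lo > hi) integer(0) else lo:hi
  }
  sz <- src(dz, n[1]); sy <- src(dy, n[2]); sx <- src(dx, n[3])
  if (!length(sz) || !length(sy) || !length(sx)) return(out)
  out[sz + dz, sy + dy, sx + dx] <- v[sz, sy, sx]
  out
}

# ball structuring-element offsets (voxel steps) for radius r mm
.ball_offsets <- function(r, spacing) {
  k <- floor(r / spacing)
  g <- expand.grid(dz = -k[1]:k[1], dy = -k[2]:k[2], dx = -k[3]:k[3])
  keep <- (g$dz * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dx * spacing[3])^2 <= r^2
  g[keep, , drop = FALSE]
}

#' Apply an autosegmentation error to a gold-standard mask
#'
#' Magnitude 0 is the identity for dilate, erode, translate and truncate.
#' Erosion (or truncation) that empties the mask returns a non-present mask
#' with status `"eroded-away"`, distinct from the `"failed"` status of a
#' model that produced nothing.
#'
#' @param gold a present [structure_mask()].
#' @param spec a [perturbation_spec()].
#' @return A [structure_mask()].
#' @export
perturb <- function(gold, spec) {
  stopifnot(inherits(gold, "structure_mask"), inherits(spec, "perturbation_spec"))
  if (!gold$present) stop("cannot perturb a non-present gold mask")
  v <- gold$values
  sp <- gold$spacing
  emptied <- function(values) structure_mask(
    values, sp, gold$origin, present = FALSE, status = "eroded-away")
  ok <- function(values) structure_mask(values, sp, gold$origin)
  switch(spec$kind,
    none = ok(v),
    fail = structure_mask(array(FALSE, dim(v)), sp, gold$origin,
                          present = FALSE, status = "failed"),
    dilate = {
      if (spec$magnitude == 0) return(ok(v))
      offs <- .ball_offsets(spec$magnitude, sp)
      acc <- array(FALSE, dim(v))
      for (i in seq_len(nrow(offs)))
        acc <- acc | .shift_mask(v, offs$dz[i], offs$dy[i], offs$dx[i])
      ok(acc)
    },
    erode = {
      if (spec$magnitude == 0) return(ok(v))
      offs <- .ball_offsets(spec$magnitude, sp)
      acc <- v
      for (i in seq_len(nrow(offs))) {
        # voxel survives only if the ball around it fits in the mask
        # (outside the grid counts as background)
        acc <- acc & .shift_mask(v, -offs$dz[i], -offs$dy[i], -offs$dx[i])
        if (!any(acc)) break
      }
      if (!any(acc)) emptied(acc) else ok(acc)
    },
    translate = {
      dv <- round(spec$magnitude / sp)
      out <- .shift_mask(v, dv[1], dv[2], dv[3])
      if (!any(out)) emptied(out) else ok(out)
    },
    truncate = {
      k <- as.integer(spec$magnitude)
      if (k == 0) return(ok(v))
      ax <- match(spec$axis, c("z", "y", "x"))
      occ_slice <- apply(v, ax, any)
      occupied <- which(occ_slice)
      drop <- utils::tail(occupied, k)
      out <- v
      idx <- list(TRUE, TRUE, TRUE); idx[[ax]] <- drop
      out <- do.call(`[<-`, c(list(out), idx, list(value = FALSE)))
      if (!any(out)) emptied(out) else ok(out)
    },
    mislocate = {
      ind <- which(v, arr.ind = TRUE)
      bb_lo <- apply(ind, 2, min); bb_hi <- apply(ind, 2, max)
      extent <- bb_hi - bb_lo + 1L
      n <- dim(v)
      for (ax in order(-(n - extent))) {   # axis with most room first
        for (sgn in c(1L, -1L)) {
          shift <- sgn * extent[ax]
          new_lo <- bb_lo[ax] + shift; new_hi <- bb_hi[ax] + shift
          if (new_lo >= 1L && new_hi <= n[ax]) {
            dv <- c(0L, 0L, 0L); dv[ax] <- shift
            out <- .shift_mask(v, dv[1], dv[2], dv[3])
            if (!any(out & v)) return(ok(out))
          }
        }
      }
      stop("mislocate: no in-grid disjoint translation exists for this mask")
    })
}
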