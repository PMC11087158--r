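#' Construct a dose grid
#'
#' A dose grid is a 3D scalar field of absorbed dose in centigray (cGy) on a
#' regular voxel lattice. Axis order is fixed as (z, y, x): the first array
#' dimension is z, the last is x. Coordinates refer to voxel centers;
#' `origin` is the physical position (mm) of the center of voxel (1,1,1).
#'
#' @param values 3D numeric array of doses, cGy, all finite and >= 0.
#' @param spacing numeric length-3, per-axis voxel size in mm (z, y, x),
#'   strictly positive.
#' @param origin numeric length-3, mm position of the first voxel center.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, spacing, origin = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L || any(dim(values) < 1L))
    stop("dose grid values must be a 3D array with every dimension >= 1")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("dose values must be finite numerics")
  if (any(values < 0)) stop("dose values must be non-negative (cGy)")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values (z, y, x)")
  if (length(origin) != 3L || anyNA(origin))
    stop("origin must be three finite mm values (z, y, x)")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Construct a binary structure mask
#'
#' A structure mask shares the dose grid's lattice convention and stores a
#' binary occupancy. A mask may represent a *failed* segmentation (the model
#' produced no structure): then `present` is `FALSE` and the occupancy is
#' empty. Failed masks are distinct from mislocated masks with Dice 0.
#'
#' @param values 3D logical (or 0/1 numeric) array.
#' @param spacing,origin as in [dose_grid()].
#' @param present logical; `FALSE` marks a failed segmentation.
#' @param status one of `"ok"`, `"failed"`, `"eroded-away"`. Defaults follow
#'   `present`.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(values, spacing, origin = c(0, 0, 0),
                           present = TRUE,
                           status = if (present) "ok" else "failed") {
  values <- as.array(values)
  if (length(dim(values)) != 3L || any(dim(values) < 1L))
    stop("mask values must be a 3D array with every dimension >= 1")
  storage.mode(values) <- "logical"
  if (anyNA(values)) stop("mask values must be 0/1 with no NA")
  status <- match.arg(status, c("ok", "failed", "eroded-away"))
  if (!present) values[] <- FALSE
  if (present && !any(values))
    stop("a present mask must contain at least one voxel")
  if (present && status != "ok") stop("present mask must have status 'ok'")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive mm values (z, y, x)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 present = isTRUE(present), status = status),
            class = "structure_mask")
}

#' Treatment protocol specification
#'
#' @param name protocol label, e.g. `"A"` or `"B"`.
#' @param prescription total prescribed dose, cGy (> 0).
#' @param fractions number of fractions (> 0).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, prescription, fractions) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("protocol name must be a non-empty string")
  prescription <- as.numeric(prescription)
  fractions <- as.integer(fractions)
  if (length(prescription) != 1L || is.na(prescription) || prescription <= 0)
    stop("prescription must be a positive dose in cGy")
  if (length(fractions) != 1L || is.na(fractions) || fractions <= 0)
    stop("fractions must be a positive count")
  structure(list(name = name, prescription = prescription,
                 fractions = fractions), class = "protocol_spec")
}

#' Default glioma VMAT protocols: A = 6000 cGy / 30#, B = 5400 cGy / 30#.
#' @return Named list of [protocol_spec()] objects.
#' @export
default_protocols <- function() {
  list(A = protocol_spec("A", 6000, 30L),
       B = protocol_spec("B", 5400, 30L))
}

#' Extract the grid header (shape, spacing, origin) of a grid or mask
#' @param g a `dose_grid` or `structure_mask`.
#' @return list with `shape`, `spacing`, `origin`.
#' @export
grid_header <- function(g) {
  stopifnot(inherits(g, c("dose_grid", "structure_mask")) ||
              (is.list(g) && all(c("shape", "spacing", "origin") %in% names(g))))
  if (inherits(g, c("dose_grid", "structure_mask")))
    list(shape = dim(g$values), spacing = g$spacing, origin = g$origin)
  else
    list(shape = as.integer(g$shape), spacing = as.numeric(g$spacing),
         origin = as.numeric(g$origin))
}

#' Header compatibility predicate
#'
#' Two grids are compatible when shapes match exactly, spacing agrees within
#' 1e-6 mm and origins agree within 1e-3 mm on every axis. Voxel values play
#' no role. Tolerances absorb floating-point header round-trips.
#'
#' @param a,b dose grids or structure masks (or plain headers).
#' @return logical scalar.
#' @export
grids_compatible <- function(a, b) {
  ha <- grid_header(a); hb <- grid_header(b)
  identical(ha$shape, hb$shape) &&
    all(abs(ha$spacing - hb$spacing) <= 1e-6) &&
    all(abs(ha$origin - hb$origin) <= 1e-3)
}

# per-axis continuous (0-based) source index of each target voxel center;
# errors when any sample falls beyond the source extent plus margin_mm
.axis_index <- function(n_t, o_t, sp_t, n_s, o_s, sp_s, margin_mm, axis) {
  coord <- o_t + (seq_len(n_t) - 1) * sp_t
  idx <- (coord - o_s) / sp_s
  lo <- -0.5 - margin_mm / sp_s
  hi <- (n_s - 1) + 0.5 + margin_mm / sp_s
  if (any(idx < lo | idx > hi))
    stop(sprintf(
      "resample target extends %.3f mm beyond the source grid on axis %s: grids do not overlap",
      max(c(lo - idx, idx - hi)) * sp_s, axis))
  idx
}

#' Resample a grid onto a target header
#'
#' Axis-aligned, same-orientation resampling between voxel lattices. Trilinear
#' interpolation is supported for dose grids only; masks always use
#' nearest-neighbor and remain binary. Sampling beyond the source grid's
#' physical extent (plus `margin_mm`) raises an error flagging non-overlapping
#' grids; within the half-voxel border, edge values are clamped.
#'
#' @param src a `dose_grid` or `structure_mask`.
#' @param target_header header list (or grid) providing shape/spacing/origin.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param margin_mm extrapolation margin beyond the half-voxel border, mm.
#' @return Object of the same class as `src` carrying the target header.
#' @export
resample_to <- function(src, target_header,
                        interpolation = c("trilinear", "nearest"),
                        margin_mm = 0) {
  interpolation <- match.arg(interpolation)
  is_mask <- inherits(src, "structure_mask")
  if (is_mask && interpolation != "nearest")
    stop("structure masks must be resampled with nearest-neighbor interpolation")
  ht <- grid_header(target_header)
  hs <- grid_header(src)
  idx <- lapply(1:3, function(a)
    .axis_index(ht$shape[a], ht$origin[a], ht$spacing[a],
                hs$shape[a], hs$origin[a], hs$spacing[a], margin_mm,
                c("z", "y", "x")[a]))
  v <- src$values
  if (interpolation == "nearest") {
    near <- lapply(1:3, function(a)
      pmin(pmax(round(idx[[a]]), 0), hs$shape[a] - 1) + 1L)
    out <- v[near[[1]], near[[2]], near[[3]], drop = FALSE]
  } else {
    i0 <- f <- vector("list", 3)
    for (a in 1:3) {
      n <- hs$shape[a]
      if (n == 1L) {
        i0[[a]] <- rep(1L, ht$shape[a]); f[[a]] <- rep(0, ht$shape[a])
      } else {
        lo <- pmin(pmax(floor(idx[[a]]), 0), n - 2)
        i0[[a]] <- as.integer(lo) + 1L
        f[[a]] <- pmin(pmax(idx[[a]] - lo, 0), 1)
      }
    }
    out <- array(0, ht$shape)
    for (az in 0:1) for (ay in 0:1) for (ax in 0:1) {
      iz <- pmin(i0[[1]] + az, hs$shape[1])
      iy <- pmin(i0[[2]] + ay, hs$shape[2])
      ix <- pmin(i0[[3]] + ax, hs$shape[3])
      wz <- if (az == 0) 1 - f[[1]] else f[[1]]
      wy <- if (ay == 0) 1 - f[[2]] else f[[2]]
      wx <- if (ax == 0) 1 - f[[3]] else f[[3]]
      w <- outer(outer(wz, wy), wx)
      out <- out + w * v[iz, iy, ix, drop = FALSE]
    }
  }
  if (is_mask) {
    storage.mode(out) <- "logical"
    if (src$present && !any(out))
      return(structure_mask(out, ht$spacing, ht$origin, present = FALSE,
                            status = "eroded-away"))
    structure_mask(out, ht$spacing, ht$origin, present = src$present,
                   status = src$status)
  } else {
    dose_grid(out, ht$spacing, ht$origin)
  }
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s voxels, spacing (%s) mm, dose %.1f-%.1f cGy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s voxels, %d occupied, status %s\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$values), x$status))
  invisible(x)
}
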