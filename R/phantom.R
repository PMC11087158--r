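#' Geometric primitive for a phantom organ-at-risk
#'
#' Shapes are axis-aligned analytic solids rasterized at voxel centers:
#' \describe{
#'   \item{sphere}{`center` (z,y,x mm), `radius` mm.}
#'   \item{ellipsoid}{`center`, `radii` (z,y,x mm).}
#'   \item{tube}{circular cylinder: `center`, `axis` (`"z"|"y"|"x"`),
#'     `radius`, `length` mm.}
#'   \item{tapered_cylinder}{as tube but radius varies linearly from
#'     `radius` at the axial start (low coordinate) to `radius2` at the end.}
#' }
#'
#' @param kind one of `"sphere"`, `"ellipsoid"`, `"tube"`,
#'   `"tapered_cylinder"`.
#' @param center numeric length-3, mm (z, y, x).
#' @param radius scalar mm (sphere, tube, tapered start radius).
#' @param radii numeric length-3 mm (ellipsoid).
#' @param axis `"z"`, `"y"` or `"x"` (tube/tapered_cylinder).
#' @param length axial length mm (tube/tapered_cylinder).
#' @param radius2 end radius mm (tapered_cylinder).
#' @return An object of class `oar_shape`.
#' @export
oar_shape <- function(kind = c("sphere", "ellipsoid", "tube",
                               "tapered_cylinder"),
                      center, radius = NULL, radii = NULL, axis = "z",
                      length = NULL, radius2 = NULL) {
  kind <- match.arg(kind)
  center <- as.numeric(center)
  stopifnot(base::length(center) == 3L)
  axis <- match.arg(axis, c("z", "y", "x"))
  sh <- list(kind = kind, center = center, radius = radius, radii = radii,
             axis = axis, length = length, radius2 = radius2)
  chk <- function(x, nm) if (is.null(x) || any(as.numeric(x) <= 0))
    stop(kind, " requires positive ", nm)
  switch(kind,
    sphere = chk(radius, "radius"),
    ellipsoid = { chk(radii, "radii"); stopifnot(base::length(radii) == 3L) },
    tube = { chk(radius, "radius"); chk(length, "length") },
    tapered_cylinder = { chk(radius, "radius"); chk(radius2, "radius2")
                         chk(length, "length") })
  structure(sh, class = "oar_shape")
}

# physical half-extent of a shape along each axis (mm), for bounds checking
.shape_extent <- function(sh) {
  ax <- match(sh$axis, c("z", "y", "x"))
  switch(sh$kind,
    sphere = rep(sh$radius, 3),
    ellipsoid = as.numeric(sh$radii),
    tube = { e <- rep(sh$radius, 3); e[ax] <- sh$length / 2; e },
    tapered_cylinder = { e <- rep(max(sh$radius, sh$radius2), 3)
                         e[ax] <- sh$length / 2; e })
}

#' Synthetic head-phantom specification
#'
#' Describes a desk-scale stand-in for a glioma VMAT case: a spherical
#' planning target volume (PTV) surrounded by a logistic dose falloff, and a
#' roster of organ-at-risk shapes at controlled distances from the dose
#' gradient. The dose model is
#' \deqn{D(x) = Rx\,[b + (1-b)\,\sigma((R - d(x))/w)]\,(1 + \epsilon)}
#' with \eqn{\sigma} the logistic function, \eqn{d(x)} the Euclidean distance
#' from the PTV center, \eqn{R} the PTV radius, \eqn{w} the gradient width,
#' \eqn{b} the background fraction of prescription and \eqn{\epsilon}
#' zero-mean Gaussian noise.
#'
#' @param shape grid dimensions (z, y, x), voxels.
#' @param spacing voxel size mm (z, y, x).
#' @param ptv_center PTV center, mm (z, y, x).
#' @param ptv_radius PTV radius R, mm.
#' @param gradient_width logistic width w, mm (dose falls from ~88% to ~12%
#'   of its dynamic range over 4w centred on d = R).
#' @param background_frac background dose fraction b of prescription,
#'   0 <= b < 1.
#' @param oars named list of [oar_shape()]s.
#' @param noise_sd fractional (multiplicative) dose noise s.d.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, ptv_center, ptv_radius,
                         gradient_width, background_frac = 0.05,
                         oars = list(), noise_sd = 0.01) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  ptv_center <- as.numeric(ptv_center)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(ptv_center) == 3L)
  if (ptv_radius <= 0) stop("ptv_radius must be > 0")
  if (gradient_width <= 0) stop("gradient_width must be > 0")
  if (background_frac < 0 || background_frac >= 1)
    stop("background_frac must satisfy 0 <= b < 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(oars) && is.null(names(oars))) stop("oars must be named")
  extent_lo <- -spacing / 2
  extent_hi <- (shape - 1) * spacing + spacing / 2
  for (nm in names(oars)) {
    sh <- oars[[nm]]
    if (!inherits(sh, "oar_shape")) stop("oars[['", nm, "']] is not an oar_shape")
    e <- .shape_extent(sh)
    if (any(sh$center - e < extent_lo) || any(sh$center + e > extent_hi))
      stop("OAR '", nm, "' extends outside the phantom grid")
  }
  structure(list(shape = shape, spacing = spacing, ptv_center = ptv_center,
                 ptv_radius = ptv_radius, gradient_width = gradient_width,
                 background_frac = background_frac, oars = oars,
                 noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Default head phantom
#'
#' A 54 x 72 x 72 grid at 2.5 mm isotropic spacing (135 x 180 x 180 mm)
#' holding the 13 organs-at-risk of a brain radiotherapy constraint table
#' (bilateral organs per side): brainstem, optic chiasm, optic nerves, orbits,
#' lenses, lacrimal glands, cochleae and pituitary. The PTV (R = 25 mm,
#' w = 5 mm, b = 0.05) sits right-posterior-superior so that the superior
#' brainstem, chiasm and posterior optic nerves straddle the dose gradient
#' while lenses, lacrimal glands, cochleae and most of the orbits lie in the
#' low-dose bath — the spatial arrangement that drives the evaluated
#' gradient-overlap behavior.
#'
#' @param noise_sd fractional dose noise s.d. (default 1%).
#' @return A [phantom_spec()].
#' @export
default_head_phantom <- function(noise_sd = 0.01) {
  oars <- list(
    brainstem = oar_shape("tapered_cylinder", center = c(52, 90, 88),
                          axis = "z", radius = 9, radius2 = 7, length = 44),
    optic_chiasm = oar_shape("ellipsoid", center = c(66, 92, 92),
                             radii = c(3.5, 5, 10)),
    optic_nerve_l = oar_shape("tapered_cylinder", center = c(66, 110, 80),
                              axis = "y", radius = 2.5, radius2 = 2,
                              length = 30),
    optic_nerve_r = oar_shape("tapered_cylinder", center = c(66, 110, 104),
                              axis = "y", radius = 2.5, radius2 = 2,
                              length = 30),
    orbit_l = oar_shape("sphere", center = c(62, 118, 62), radius = 12),
    orbit_r = oar_shape("sphere", center = c(62, 118, 122), radius = 12),
    lens_l = oar_shape("sphere", center = c(62, 132, 62), radius = 4),
    lens_r = oar_shape("sphere", center = c(62, 132, 122), radius = 4),
    lacrimal_l = oar_shape("ellipsoid", center = c(70, 120, 48),
                           radii = c(4, 5, 6)),
    lacrimal_r = oar_shape("ellipsoid", center = c(70, 120, 136),
                           radii = c(4, 5, 6)),
    cochlea_l = oar_shape("sphere", center = c(52, 75, 60), radius = 3.5),
    cochlea_r = oar_shape("sphere", center = c(52, 75, 140), radius = 3.5),
    pituitary = oar_shape("sphere", center = c(60, 90, 96), radius = 5)
  )
  phantom_spec(shape = c(54, 72, 72), spacing = c(2.5, 2.5, 2.5),
               ptv_center = c(78, 80, 100), ptv_radius = 25,
               gradient_width = 5, background_frac = 0.05,
               oars = oars, noise_sd = noise_sd)
}

# squared distance of every voxel center from a point, as a (z,y,x) array
.dist2_field <- function(shape, spacing, origin, center) {
  d1 <- (origin[1] + (seq_len(shape[1]) - 1) * spacing[1] - center[1])^2
  d2 <- (origin[2] + (seq_len(shape[2]) - 1) * spacing[2] - center[2])^2
  d3 <- (origin[3] + (seq_len(shape[3]) - 1) * spacing[3] - center[3])^2
  outer(outer(d1, d2, "+"), d3, "+")
}

#' Generate the phantom dose field
#'
#' Evaluates the logistic VMAT-like dose model of [phantom_spec()] for a given
#' protocol, with multiplicative Gaussian noise (zero-mean, s.d.
#' `phantom$noise_sd`, seed-reproducible). Noise-free dose is monotone
#' non-increasing in distance from the PTV center.
#'
#' @param phantom a [phantom_spec()].
#' @param protocol a [protocol_spec()].
#' @param seed integer RNG seed for the noise draw.
#' @return A [dose_grid()], cGy.
#' @export
generate_dose <- function(phantom, protocol, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(protocol, "protocol_spec"))
  d <- sqrt(.dist2_field(phantom$shape, phantom$spacing, c(0, 0, 0),
                         phantom$ptv_center))
  b <- phantom$background_frac
  base <- protocol$prescription *
    (b + (1 - b) * stats::plogis((phantom$ptv_radius - d) /
                                   phantom$gradient_width))
  if (phantom$noise_sd > 0) {
    old <- .Random.seed_guard(seed)
    on.exit(old(), add = TRUE)
    base <- base * (1 + stats::rnorm(length(base), 0, phantom$noise_sd))
  }
  dose_grid(pmax(base, 0), phantom$spacing, c(0, 0, 0))
}

# run code under a local RNG seed, restoring global state afterwards
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# rasterize one shape at voxel centers -> logical array
.rasterize_shape <- function(sh, shape, spacing) {
  cz <- (seq_len(shape[1]) - 1) * spacing[1]
  cy <- (seq_len(shape[2]) - 1) * spacing[2]
  cx <- (seq_len(shape[3]) - 1) * spacing[3]
  switch(sh$kind,
    sphere = .dist2_field(shape, spacing, c(0, 0, 0), sh$center) <=
      sh$radius^2,
    ellipsoid = {
      t1 <- ((cz - sh$center[1]) / sh$radii[1])^2
      t2 <- ((cy - sh$center[2]) / sh$radii[2])^2
      t3 <- ((cx - sh$center[3]) / sh$radii[3])^2
      outer(outer(t1, t2, "+"), t3, "+") <= 1
    },
    tube = ,
    tapered_cylinder = {
      ax <- match(sh$axis, c("z", "y", "x"))
      others <- setdiff(1:3, ax)
      coords <- list(cz, cy, cx)
      axial <- coords[[ax]] - sh$center[ax]
      within_len <- abs(axial) <= sh$length / 2
      r_at <- if (sh$kind == "tube") rep(sh$radius, length(axial))
        else sh$radius + (sh$radius2 - sh$radius) *
          (axial + sh$length / 2) / sh$length
      rad2 <- outer((coords[[others[1]]] - sh$center[others[1]])^2,
                    (coords[[others[2]]] - sh$center[others[2]])^2, "+")
      occ <- outer(r_at^2, rad2, ">=") & within_len   # (axial, o1, o2)
      perm <- integer(3); perm[ax] <- 1L; perm[others] <- c(2L, 3L)
      aperm(occ, perm)
    })
}

#' Rasterize the phantom's gold-standard structure set
#'
#' @param phantom a [phantom_spec()] with at least one OAR.
#' @return Named list of present [structure_mask()]s, one per OAR.
#' @export
generate_structures <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_spec"))
  if (!length(phantom$oars)) stop("phantom has no OARs configured")
  out <- lapply(phantom$oars, function(sh) {
    occ <- .rasterize_shape(sh, phantom$shape, phantom$spacing)
    if (!any(occ))
      stop("OAR rasterized to an empty mask (shape smaller than one voxel?)")
    structure_mask(occ, phantom$spacing, c(0, 0, 0))
  })
  out
}
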