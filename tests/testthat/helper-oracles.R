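# Independent oracles and fixture builders. These deliberately re-derive
# every quantity with the dumbest correct algorithm (full sorts, double
# loops) and never call package internals.

# D_x% oracle: descending sort, linear scan of cumulative volume fraction
dvh_oracle <- function(doses, x_percent) {
  s <- sort(doses, decreasing = TRUE)
  n <- length(s)
  cum <- seq_len(n) / n
  s[which(cum >= x_percent / 100)[1]]
}

# surface voxels (face adjacency; outside the grid counts as unoccupied),
# as an n x 3 index matrix
surface_oracle <- function(v) {
  n <- dim(v)
  ind <- which(v, arr.ind = TRUE)
  keep <- logical(nrow(ind))
  for (i in seq_len(nrow(ind))) {
    z <- ind[i, 1]; y <- ind[i, 2]; x <- ind[i, 3]
    nb <- list(c(z - 1, y, x), c(z + 1, y, x), c(z, y - 1, x),
               c(z, y + 1, x), c(z, y, x - 1), c(z, y, x + 1))
    for (p in nb) {
      if (any(p < 1) || any(p > n) || !v[p[1], p[2], p[3]]) {
        keep[i] <- TRUE; break
      }
    }
  }
  ind[keep, , drop = FALSE]
}

# symmetric mean surface distance by exhaustive O(n^2) pairwise search
mda_oracle <- function(gold, auto) {
  sg <- surface_oracle(gold$values)
  sa <- surface_oracle(auto$values)
  sp <- gold$spacing
  mmg <- sweep(sg - 1, 2, sp, "*")
  mma <- sweep(sa - 1, 2, sp, "*")
  one_way <- function(a, b) {
    out <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
      best <- Inf
      for (j in seq_len(nrow(b))) {
        d2 <- sum((a[i, ] - b[j, ])^2)
        if (d2 < best) best <- d2
      }
      out[i] <- sqrt(best)
    }
    out
  }
  dag <- one_way(mma, mmg)
  dga <- one_way(mmg, mma)
  (sum(dag) + sum(dga)) / (length(dag) + length(dga))
}

dsc_oracle <- function(gold, auto) {
  g <- gold$values; a <- auto$values
  2 * sum(g & a) / (sum(g) + sum(a))
}

sens_oracle <- function(gold, auto) {
  sum(gold$values & auto$values) / sum(gold$values)
}

# random dose grid + random non-empty mask on a shared small lattice
rand_field_mask <- function(max_dim = 10, spacing = c(1, 2, 0.5)) {
  dims <- sample(2:max_dim, 3, replace = TRUE)
  d <- dose_grid(array(stats::runif(prod(dims), 0, 7000), dims), spacing)
  occ <- array(stats::runif(prod(dims)) < 0.4, dims)
  if (!any(occ)) occ[sample(length(occ), 1)] <- TRUE
  list(dose = d, mask = structure_mask(occ, spacing))
}

# random connected-ish blob mask pair on a cube lattice (<= max_dim^3)
rand_mask_pair <- function(max_dim = 12, spacing = c(1, 1.5, 2)) {
  dims <- rep(sample(4:max_dim, 1), 3)
  blob <- function() {
    c0 <- stats::runif(3, 2, dims - 1)
    r <- stats::runif(1, 1.5, dims / 2)
    idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                 seq_len(dims[3])))
    occ <- array(colSums((t(idx) - c0)^2) <= r^2, dims)
    if (!any(occ)) occ[ceiling(length(occ) / 2)] <- TRUE
    occ
  }
  list(gold = structure_mask(blob(), spacing),
       auto = structure_mask(blob(), spacing))
}

# small two-organ phantom for fast end-to-end tests; organ names reuse the
# default constraint table so the default config applies
tiny_phantom <- function(noise_sd = 0) {
  phantom_spec(
    shape = c(20, 24, 24), spacing = c(4, 4, 4),
    ptv_center = c(40, 48, 40), ptv_radius = 15, gradient_width = 5,
    background_frac = 0.05,
    oars = list(
      brainstem = oar_shape("tube", center = c(36, 48, 64), axis = "z",
                            radius = 8, length = 32),
      cochlea_l = oar_shape("sphere", center = c(20, 20, 20), radius = 6),
      lens_l = oar_shape("sphere", center = c(64, 76, 76), radius = 5)),
    noise_sd = noise_sd)
}

# perturbation-free profiles (identity pipeline)
identity_profiles <- function(models = c("m1", "m2")) {
  pr <- error_profile("none", 1)
  stats::setNames(rep(list(pr), length(models)), models)
}
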