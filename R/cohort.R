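#' Autosegmentation model error profile
#'
#' A distribution over [perturbation_spec()]s from which a simulated model's
#' per-organ error is drawn. Each row of the profile carries a kind, a
#' sampling probability and a magnitude range (uniform; for `translate` the
#' magnitude is a displacement of uniform length in a random axis-aligned
#' direction, which keeps shifts aligned with the voxel lattice).
#'
#' @param kinds character vector of perturbation kinds.
#' @param probs sampling probabilities (same length, summing to 1 within
#'   1e-6).
#' @param min_mag,max_mag magnitude ranges, mm (or slices for truncate);
#'   ignored for none/mislocate/fail.
#' @return data.frame of class `error_profile`.
#' @export
error_profile <- function(kinds, probs, min_mag = 0, max_mag = 0) {
  kinds <- match.arg(kinds, c("none", "dilate", "erode", "translate",
                              "truncate", "mislocate", "fail"),
                     several.ok = TRUE)
  stopifnot(length(probs) == length(kinds))
  if (abs(sum(probs) - 1) > 1e-6) stop("profile probabilities must sum to 1")
  df <- data.frame(kind = kinds, prob = as.numeric(probs),
                   min_mag = rep_len(as.numeric(min_mag), length(kinds)),
                   max_mag = rep_len(as.numeric(max_mag), length(kinds)),
                   stringsAsFactors = FALSE)
  class(df) <- c("error_profile", "data.frame")
  df
}

#' Default model error profiles
#'
#' Two stereotyped models bracketing the behavior seen when training contours
#' are or are not curated: `"edited"` (mostly faithful, occasional moderate
#' morphological error, ~5% outright failure) and `"unedited"` (larger and
#' more frequent errors including gross mislocation). Failure probabilities of
#' about 5-15% echo per-organ success counts of roughly 6-10 out of 9-10
#' cases reported for such models.
#'
#' @return Named list of [error_profile()]s keyed by model name.
#' @export
default_error_profiles <- function() {
  list(
    edited = error_profile(
      kinds = c("none", "dilate", "erode", "translate", "truncate", "fail"),
      probs = c(0.40, 0.15, 0.10, 0.20, 0.10, 0.05),
      min_mag = c(0, 1.0, 1.0, 1.0, 1, 0),
      max_mag = c(0, 3.0, 2.5, 4.0, 3, 0)),
    unedited = error_profile(
      kinds = c("none", "dilate", "erode", "translate", "truncate",
                "mislocate", "fail"),
      probs = c(0.20, 0.20, 0.15, 0.20, 0.10, 0.05, 0.10),
      min_mag = c(0, 1.5, 1.0, 2.0, 1, 0, 0),
      max_mag = c(0, 5.0, 3.0, 7.5, 4, 0, 0))
  )
}

# draw one perturbation_spec from a profile (uses the current RNG stream)
.draw_perturbation <- function(profile, spacing) {
  row <- profile[sample.int(nrow(profile), 1, prob = profile$prob), ]
  kind <- row$kind
  if (kind %in% c("none", "mislocate", "fail"))
    return(perturbation_spec(kind))
  mag <- stats::runif(1, row$min_mag, row$max_mag)
  if (kind == "truncate")
    return(perturbation_spec("truncate", magnitude = max(1, round(mag)),
                             axis = sample(c("z", "y", "x"), 1)))
  if (kind == "translate") {
    vec <- c(0, 0, 0)
    ax <- sample.int(3, 1)
    vec[ax] <- sample(c(-1, 1), 1) * max(mag, spacing[ax]) # >= 1 voxel
    return(perturbation_spec("translate", magnitude = vec))
  }
  perturbation_spec(kind, magnitude = mag)
}

#' Simulate a synthetic evaluation cohort
#'
#' Generates `n_cases` phantom cases: per case a protocol label, a dose grid
#' (with per-case jitter of the PTV center and radius so that gold doses and
#' headrooms vary across the cohort), the shared gold structure set, and one
#' drawn perturbation per model and organ. Auto masks are materialized on
#' demand ([case_bundle()]), deterministically from the stored specs, to keep
#' large cohorts in memory. The whole cohort is a pure function of
#' (arguments, `seed`).
#'
#' @param n_cases number of cases (>= 1).
#' @param phantom a [phantom_spec()]; default [default_head_phantom()].
#' @param model_profiles named list of [error_profile()]s (non-empty).
#' @param seed integer seed.
#' @param protocols named list of [protocol_spec()]s.
#' @param prob_protocol_a probability a case is assigned the first protocol.
#' @param ptv_center_jitter_sd,ptv_radius_jitter_sd per-case anatomical
#'   jitter, mm.
#' @return An object of class `oar_cohort`.
#' @export
simulate_cohort <- function(n_cases,
                            phantom = default_head_phantom(),
                            model_profiles = default_error_profiles(),
                            seed = 1L,
                            protocols = default_protocols(),
                            prob_protocol_a = 0.6,
                            ptv_center_jitter_sd = 3,
                            ptv_radius_jitter_sd = 2) {
  stopifnot(n_cases >= 1, inherits(phantom, "phantom_spec"))
  if (!length(model_profiles) || is.null(names(model_profiles)))
    stop("model_profiles must be a non-empty named list of error profiles")
  if (!length(phantom$oars)) stop("phantom has no OARs configured")
  restore <- .Random.seed_guard(as.integer(seed))
  on.exit(restore(), add = TRUE)

  gold <- generate_structures(phantom)
  organs <- names(gold)
  models <- names(model_profiles)
  cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    proto_name <- if (stats::runif(1) < prob_protocol_a) names(protocols)[1]
      else names(protocols)[2]
    jitter_c <- stats::rnorm(3, 0, ptv_center_jitter_sd)
    jitter_r <- stats::rnorm(1, 0, ptv_radius_jitter_sd)
    ph_i <- phantom
    ph_i$ptv_center <- phantom$ptv_center + jitter_c
    ph_i$ptv_radius <- max(phantom$ptv_radius + jitter_r,
                           phantom$gradient_width)
    noise_seed <- sample.int(.Machine$integer.max - 1L, 1)
    perturbations <- lapply(model_profiles, function(pr) {
      ps <- lapply(organs, function(o) .draw_perturbation(pr, phantom$spacing))
      names(ps) <- organs
      ps
    })
    cases[[i]] <- list(id = sprintf("case%03d", i),
                       protocol = proto_name,
                       phantom = ph_i,
                       noise_seed = noise_seed,
                       perturbations = perturbations)
  }
  structure(list(cases = cases, gold = gold, organs = organs,
                 models = models, protocols = protocols,
                 phantom = phantom, seed = as.integer(seed)),
            class = "oar_cohort")
}

#' Case identifiers of a cohort
#' @param cohort an `oar_cohort` or file-backed cohort handle.
#' @return character vector of case ids.
#' @export
cohort_case_ids <- function(cohort) {
  vapply(cohort$cases, `[[`, character(1), "id")
}

#' Materialize one case of a cohort
#'
#' Returns the dose grid, the gold structure set and the per-model auto
#' structure sets of a single case. For simulated cohorts, dose and auto masks
#' are regenerated deterministically from the stored specs; for file-backed
#' cohorts ([load_cohort()]) grids are read from disk.
#'
#' @param cohort a cohort object.
#' @param id case id (see [cohort_case_ids()]).
#' @return list with `id`, `protocol`, `dose`, `gold` (named mask list) and
#'   `auto` (model -> named mask list).
#' @export
case_bundle <- function(cohort, id) {
  UseMethod("case_bundle")
}

#' @export
case_bundle.oar_cohort <- function(cohort, id) {
  ids <- cohort_case_ids(cohort)
  i <- match(id, ids)
  if (is.na(i)) stop("unknown case id: ", id)
  cs <- cohort$cases[[i]]
  dose <- generate_dose(cs$phantom, cohort$protocols[[cs$protocol]],
                        seed = cs$noise_seed)
  auto <- lapply(cs$perturbations, function(per_model)
    mapply(function(g, sp) perturb(g, sp), cohort$gold, per_model,
           SIMPLIFY = FALSE))
  list(id = cs$id, protocol = cs$protocol, dose = dose,
       gold = cohort$gold, auto = auto)
}
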