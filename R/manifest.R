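#' Write a cohort to disk (NIfTI grids + JSON manifest)
#'
#' Materializes every case of a simulated cohort as a directory tree:
#' `<dir>/<case>/dose.nii`, `<dir>/<case>/gold/<organ>.nii`,
#' `<dir>/<case>/auto/<model>/<organ>.nii` (failed organs get no file, only a
#' status marker in the manifest), plus `<dir>/manifest.json` recording case
#' ids, protocol labels, per-file paths and statuses. Writing is
#' deterministic: the same cohort yields byte-identical manifests.
#'
#' @param cohort an `oar_cohort` from [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "oar_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  protocols <- lapply(cohort$protocols, function(p)
    list(name = p$name, prescription_cGy = p$prescription,
         fractions = p$fractions))
  case_records <- list()
  for (id in cohort_case_ids(cohort)) {
    cb <- case_bundle(cohort, id)
    cdir <- file.path(dir, id)
    dir.create(file.path(cdir, "gold"), recursive = TRUE,
               showWarnings = FALSE)
    dose_rel <- file.path(id, "dose.nii")
    write_nifti(cb$dose, file.path(dir, dose_rel))
    gold_rec <- list()
    for (organ in names(cb$gold)) {
      rel <- file.path(id, "gold", paste0(organ, ".nii"))
      write_nifti(cb$gold[[organ]], file.path(dir, rel))
      gold_rec[[organ]] <- rel
    }
    auto_rec <- list()
    for (model in names(cb$auto)) {
      mdir <- file.path(cdir, "auto", model)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      organs_rec <- list()
      for (organ in names(cb$auto[[model]])) {
        m <- cb$auto[[model]][[organ]]
        if (m$present) {
          rel <- file.path(id, "auto", model, paste0(organ, ".nii"))
          write_nifti(m, file.path(dir, rel))
          organs_rec[[organ]] <- list(path = rel, status = m$status)
        } else {
          organs_rec[[organ]] <- list(path = NULL, status = m$status)
        }
      }
      auto_rec[[model]] <- organs_rec
    }
    case_records[[length(case_records) + 1L]] <-
      list(id = id, protocol = cb$protocol, dose = dose_rel,
           gold = gold_rec, auto = auto_rec)
  }
  manifest <- list(schema_version = 1L,
                   generator = "oardose",
                   seed = cohort$seed,
                   protocols = protocols,
                   models = as.list(cohort$models),
                   organs = as.list(cohort$organs),
                   cases = case_records)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Load a cohort from a manifest
#'
#' Validates the manifest (supported schema version, unique case ids, every
#' referenced file existing — a missing auto file without a failed status is
#' an error naming the case and organ) and returns a file-backed cohort
#' handle. Grids are read lazily, per case, by [case_bundle()]; grid
#' compatibility is checked when a case is evaluated.
#'
#' @param manifest_path path to `manifest.json`.
#' @return An object of class `oar_cohort_files`.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  if (is.null(man$schema_version) || man$schema_version != 1L)
    stop("unsupported manifest schema version: ",
         format(man$schema_version))
  root <- dirname(normalizePath(manifest_path))
  ids <- vapply(man$cases, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate case ids in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  proto_names <- vapply(man$protocols, `[[`, character(1), "name")
  for (cs in man$cases) {
    if (!cs$protocol %in% proto_names)
      stop("case ", cs$id, ": unknown protocol label '", cs$protocol, "'")
    paths <- c(cs$dose, unlist(cs$gold, use.names = FALSE))
    for (p in paths)
      if (!file.exists(file.path(root, p)))
        stop("case ", cs$id, ": missing file ", p)
    for (model in names(cs$auto)) for (organ in names(cs$auto[[model]])) {
      rec <- cs$auto[[model]][[organ]]
      if (is.null(rec$path)) {
        if (is.null(rec$status) || rec$status == "ok")
          stop("case ", cs$id, ", organ ", organ, ", model ", model,
               ": no auto file and no failed marker")
      } else if (!file.exists(file.path(root, rec$path))) {
        stop("case ", cs$id, ", organ ", organ, ", model ", model,
             ": missing auto file ", rec$path)
      }
    }
  }
  protocols <- lapply(man$protocols, function(p)
    protocol_spec(p$name, p$prescription_cGy, p$fractions))
  names(protocols) <- proto_names
  structure(list(root = root,
                 cases = man$cases,
                 organs = unlist(man$organs),
                 models = unlist(man$models),
                 protocols = protocols,
                 seed = man$seed),
            class = "oar_cohort_files")
}

#' @export
case_bundle.oar_cohort_files <- function(cohort, id) {
  ids <- vapply(cohort$cases, `[[`, character(1), "id")
  i <- match(id, ids)
  if (is.na(i)) stop("unknown case id: ", id)
  cs <- cohort$cases[[i]]
  root <- cohort$root
  dose <- read_nifti(file.path(root, cs$dose), as = "dose")
  gold <- lapply(cs$gold, function(p)
    read_nifti(file.path(root, p), as = "mask"))
  auto <- lapply(cs$auto, function(per_model)
    lapply(per_model, function(rec) {
      if (is.null(rec$path)) {
        structure_mask(array(FALSE, dim(dose$values)), dose$spacing,
                       dose$origin, present = FALSE, status = rec$status)
      } else {
        read_nifti(file.path(root, rec$path), as = "mask")
      }
    }))
  list(id = cs$id, protocol = cs$protocol, dose = dose, gold = gold,
       auto = auto)
}
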