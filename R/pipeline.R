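#' Pipeline run configuration
#'
#' Bundles every threshold-relevant setting: the organ constraint table, the
#' protocol definitions, the percent-change normalization, the
#' boundary/tie conventions, the significance level and Bonferroni family
#' size, and the seed. The config fingerprint ([config_fingerprint()])
#' changes whenever any of these change.
#'
#' @param oar_table constraint table, default [default_oar_table()].
#' @param protocols named list of [protocol_spec()]s.
#' @param percent_norm `"gold"` (percent change relative to the gold metric,
#'   default) or `"prescription"` (relative to the protocol prescription).
#' @param mean_like_rule see [significance_report()].
#' @param alpha family-wise significance level.
#' @param family_size optional Bonferroni family-size override (default: the
#'   number of model pairs in the cohort).
#' @param alpha_override optional fixed corrected alpha (printed-convention
#'   override, e.g. 0.01).
#' @param seed integer seed recorded in the run log.
#' @return list of class `run_config`.
#' @export
run_config <- function(oar_table = default_oar_table(),
                       protocols = default_protocols(),
                       percent_norm = c("gold", "prescription"),
                       mean_like_rule = c("T", "T/2"),
                       alpha = 0.05, family_size = NULL,
                       alpha_override = NULL, seed = 1L) {
  percent_norm <- match.arg(percent_norm)
  mean_like_rule <- match.arg(mean_like_rule)
  stopifnot(alpha > 0, alpha < 1)
  cfg <- list(oar_table = oar_table, protocols = protocols,
              percent_norm = percent_norm, mean_like_rule = mean_like_rule,
              alpha = alpha, family_size = family_size,
              alpha_override = alpha_override, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Fingerprint of a run configuration
#'
#' 64-bit FNV-1a hash of the canonical JSON serialization of every
#' threshold-relevant setting; any change to the config changes the
#' fingerprint (no silent reconfiguration).
#'
#' @param config a [run_config()].
#' @return 16-hex-digit string.
#' @export
config_fingerprint <- function(config) {
  stopifnot(inherits(config, "run_config"))
  canon <- list(
    oar_table = config$oar_table[order(config$oar_table$organ), ],
    protocols = lapply(config$protocols, function(p)
      list(p$name, p$prescription, p$fractions)),
    percent_norm = config$percent_norm,
    mean_like_rule = config$mean_like_rule,
    alpha = config$alpha, family_size = config$family_size,
    alpha_override = config$alpha_override)
  s <- as.character(jsonlite::toJSON(canon, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(s)
  # FNV-1a, 64-bit carried as two 32-bit halves to stay in double precision
  hi <- 0xcbf29ce4; lo <- 0x84222325
  p_hi <- 0x00000100; p_lo <- 0x000001b3
  for (b in bytes) {
    # xor on the low byte only (ASCII input), avoiding 32-bit int overflow
    lo <- (lo - lo %% 256) + bitwXor(lo %% 256, b %% 256)
    # (hi,lo) * (p_hi,p_lo) mod 2^64, via 16-bit limbs
    a <- c(lo %% 65536, lo %/% 65536, hi %% 65536, hi %/% 65536)
    m <- c(p_lo %% 65536, p_lo %/% 65536, p_hi %% 65536, p_hi %/% 65536)
    r <- numeric(4)
    for (i in 1:4) for (j in 1:4) if (i + j - 1 <= 4)
      r[i + j - 1] <- r[i + j - 1] + a[i] * m[j]
    for (i in 1:3) { r[i + 1] <- r[i + 1] + r[i] %/% 65536; r[i] <- r[i] %% 65536 }
    r[4] <- r[4] %% 65536
    lo <- r[1] + r[2] * 65536
    hi <- r[3] + r[4] * 65536
  }
  sprintf("%04x%04x%04x%04x",
          as.integer(hi %/% 65536), as.integer(hi %% 65536),
          as.integer(lo %/% 65536), as.integer(lo %% 65536))
}

#' Evaluate a cohort case by case
#'
#' For every case x model x organ, computes the organ's DVH statistic on the
#' gold and auto masks, the dose delta, and the geometric agreement metrics.
#' Failed segmentations propagate their status and carry no geometry.
#'
#' @param cohort an `oar_cohort` or `oar_cohort_files`.
#' @param config a [run_config()].
#' @param quiet suppress per-case progress messages.
#' @return data.frame (one row per case x model x organ): case_id, protocol,
#'   model, organ, metric, gold_cGy, auto_cGy, delta_cGy, percent,
#'   abs_percent, dsc, sensitivity, mean_dta_mm, status.
#' @export
evaluate_cohort <- function(cohort, config = run_config(), quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  oar_table <- config$oar_table
  ids <- cohort_case_ids(cohort)
  rows <- vector("list", 0L)
  for (id in ids) {
    cb <- case_bundle(cohort, id)
    if (!quiet) message("evaluating ", id)
    rx <- cohort$protocols[[cb$protocol]]$prescription
    for (organ in names(cb$gold)) {
      spec <- oar_table[oar_table$organ == organ, ]
      if (!nrow(spec))
        stop("case ", id, ": organ '", organ,
             "' missing from the constraint table")
      gold <- cb$gold[[organ]]
      if (!grids_compatible(cb$dose, gold))
        stop("case ", id, ", organ ", organ,
             ": gold mask incompatible with dose grid")
      for (model in names(cb$auto)) {
        auto <- cb$auto[[model]][[organ]]
        if (is.null(auto))
          stop("case ", id, ", model ", model, ": organ '", organ,
               "' missing from auto set")
        dd <- dose_delta(cb$dose, gold, auto, spec$metric,
                         percent_ref = if (config$percent_norm ==
                                           "prescription") rx else NULL)
        gm <- geometry_metrics(gold, auto)
        status <- if (dd$status != "ok") dd$status else gm$status
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = id, protocol = cb$protocol, model = model,
          organ = organ, metric = spec$metric,
          gold_cGy = dd$gold_cGy, auto_cGy = dd$auto_cGy,
          delta_cGy = dd$delta_cGy, percent = dd$percent,
          abs_percent = dd$abs_percent,
          dsc = gm$dsc, sensitivity = gm$sensitivity,
          mean_dta_mm = gm$mean_dta_mm,
          status = status, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full evaluation pipeline
#'
#' Composes the per-case evaluation, the cohort aggregation table, the
#' clinical-significance report, the paired model comparisons and the
#' geometric-dosimetric correlations. Deterministic given cohort + config.
#' When `out_dir` is given, writes `per_case.csv`, `cohort_table.csv`,
#' `significance.csv`, `model_tests.csv`, `correlations.csv` and a
#' machine-readable `run_log.json` (config, fingerprint, seeds, package
#' version, warning codes).
#'
#' @param cohort an `oar_cohort` or `oar_cohort_files`.
#' @param config a [run_config()].
#' @param out_dir optional output directory for report files.
#' @return list with elements `per_case`, `cohort_table`, `significance`,
#'   `model_tests`, `correlations`, `run_log`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  per_case <- evaluate_cohort(cohort, config)
  cohort_table <- aggregate_deltas(per_case)
  signif_rep <- significance_report(per_case, config$oar_table,
                                    mean_like_rule = config$mean_like_rule)
  model_tests <- if (length(unique(per_case$model)) >= 2)
    model_comparisons(per_case, alpha = config$alpha,
                      family_size = config$family_size,
                      alpha_override = config$alpha_override)
  else NULL
  correlations <- correlate_geometry_dose(per_case)
  warnings <- character(0)
  if (any(signif_rep$excluded_reason %in% "negative headroom"))
    warnings <- c(warnings, "W_NEGATIVE_HEADROOM")
  if (any(per_case$status == "undefined-percent"))
    warnings <- c(warnings, "W_UNDEFINED_PERCENT")
  if (!is.null(model_tests) && any(!model_tests$available))
    warnings <- c(warnings, "W_TEST_UNAVAILABLE")
  if (any(!correlations$available))
    warnings <- c(warnings, "W_CORRELATION_UNDEFINED")
  run_log <- list(
    package = "oardose",
    version = as.character(utils::packageVersion("oardose")),
    config_fingerprint = config_fingerprint(config),
    percent_norm = config$percent_norm,
    mean_like_rule = config$mean_like_rule,
    alpha = config$alpha,
    alpha_override = config$alpha_override,
    seed = config$seed,
    n_cases = length(cohort_case_ids(cohort)),
    models = sort(unique(per_case$model)),
    organs = sort(unique(per_case$organ)),
    warnings = warnings)
  out <- list(per_case = per_case, cohort_table = cohort_table,
              significance = signif_rep, model_tests = model_tests,
              correlations = correlations, run_log = run_log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      if (!is.null(df))
        utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    wcsv(per_case, "per_case.csv")
    wcsv(cohort_table, "cohort_table.csv")
    wcsv(signif_rep, "significance.csv")
    wcsv(model_tests, "model_tests.csv")
    wcsv(correlations, "correlations.csv")
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  }
  out
}
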