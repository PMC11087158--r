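#' @title Cohort-level aggregation and inference
#' @description Absolute-average dose-change tables with success counts N*,
#'   paired two-tailed Student t comparisons between models with Bonferroni
#'   control, and Pearson correlations between geometric agreement and
#'   absolute percent dose change.
#' @name cohort_stats
NULL

#' Aggregate per-case dose deltas into a cohort table
#'
#' Per model x organ: mean absolute percent dose change over successfully
#' segmented cases (N*), with failed and undefined-percent cases excluded
#' from the mean and tallied separately. `N* + n_failed` equals the cohort
#' size for every row.
#'
#' @param per_case table with columns case_id, model, organ, abs_percent,
#'   status.
#' @return data.frame: model, organ, mean_abs_percent, n_star, n_failed,
#'   n_undefined_percent.
#' @export
aggregate_deltas <- function(per_case) {
  needed <- c("case_id", "model", "organ", "abs_percent", "status")
  if (!all(needed %in% names(per_case)))
    stop("per_case table lacks columns: ",
         paste(setdiff(needed, names(per_case)), collapse = ", "))
  keys <- unique(per_case[, c("model", "organ")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- per_case[per_case$model == keys$model[i] &
                      per_case$organ == keys$organ[i], ]
    failed <- sub$status %in% c("failed", "eroded-away")
    undef <- sub$status == "undefined-percent"
    okv <- sub$abs_percent[sub$status == "ok"]
    data.frame(model = keys$model[i], organ = keys$organ[i],
               mean_abs_percent = if (length(okv)) mean(okv) else NA_real_,
               n_star = sum(!failed), n_failed = sum(failed),
               n_undefined_percent = sum(undef), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$model, out$organ), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Paired two-tailed Student t-test between two models
#'
#' Classical paired t on the per-case differences `a - b`, with Bonferroni
#' correction `alpha / family_size`. Fewer than 2 complete pairs or
#' zero-variance differences make the test unavailable (`NA` statistics,
#' never a silent p of 0 or 1). The effect size is the difference of the two
#' models' median values.
#'
#' @param a,b paired per-case values (equal length; `NA`s drop the pair).
#' @param family_size number of pairwise comparisons in the family (e.g. 3
#'   for three models compared pairwise, 1 for two models).
#' @param alpha family-wise significance level.
#' @param alpha_override optional fixed corrected alpha (e.g. 0.01 to
#'   reproduce a rounded printed convention) in place of
#'   `alpha / family_size`.
#' @return one-row data.frame: n_pairs, t, df, p, corrected_alpha,
#'   significant, effect_size_median_diff, available.
#' @export
paired_model_test <- function(a, b, family_size = 1L, alpha = 0.05,
                              alpha_override = NULL) {
  stopifnot(length(a) == length(b), family_size >= 1, alpha > 0)
  keep <- stats::complete.cases(a, b)
  a <- as.numeric(a[keep]); b <- as.numeric(b[keep])
  corrected <- if (is.null(alpha_override)) alpha / family_size
               else as.numeric(alpha_override)
  eff <- if (length(a)) stats::median(a) - stats::median(b) else NA_real_
  d <- a - b
  n <- length(d)
  if (n < 2 || stats::sd(d) == 0) {
    return(data.frame(n_pairs = n, t = NA_real_, df = NA_real_, p = NA_real_,
                      corrected_alpha = corrected, significant = NA,
                      effect_size_median_diff = eff, available = FALSE,
                      stringsAsFactors = FALSE))
  }
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(n_pairs = n, t = tstat, df = df, p = p,
             corrected_alpha = corrected,
             significant = p <= corrected,
             effect_size_median_diff = eff, available = TRUE,
             stringsAsFactors = FALSE)
}

#' All pairwise model comparisons per organ
#'
#' Pairs every model combination per organ on percent dose change, with
#' pairwise-complete deletion (a failed segmentation drops the pair, not the
#' case's other organs). The family size defaults to the number of model
#' pairs.
#'
#' @param per_case table with case_id, model, organ, percent, status.
#' @param alpha family-wise level.
#' @param family_size override of the Bonferroni family size.
#' @param alpha_override see [paired_model_test()].
#' @return data.frame, one row per organ x model pair.
#' @export
model_comparisons <- function(per_case, alpha = 0.05, family_size = NULL,
                              alpha_override = NULL) {
  models <- sort(unique(per_case$model))
  if (length(models) < 2) stop("need at least two models to compare")
  prs <- utils::combn(models, 2, simplify = FALSE)
  if (is.null(family_size)) family_size <- length(prs)
  rows <- list()
  for (organ in unique(per_case$organ)) {
    sub <- per_case[per_case$organ == organ, ]
    for (pr in prs) {
      wa <- sub[sub$model == pr[1], c("case_id", "percent")]
      wb <- sub[sub$model == pr[2], c("case_id", "percent")]
      m <- merge(wa, wb, by = "case_id", suffixes = c("_a", "_b"))
      res <- paired_model_test(m$percent_a, m$percent_b,
                               family_size = family_size, alpha = alpha,
                               alpha_override = alpha_override)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(organ = organ, model_a = pr[1], model_b = pr[2],
                   stringsAsFactors = FALSE), res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between a geometric metric and absolute percent dose
#' change
#'
#' Points are pooled across organs and cases within one model; pairs with a
#' failed segmentation or undefined percent are dropped pairwise. The
#' two-tailed p-value uses the t transform `t = r sqrt((n-2)/(1-r^2))` when
#' `n >= 3`; with `n < 3` the r is reported and p is unavailable. Zero
#' variance in either coordinate leaves the correlation undefined and
#' flagged.
#'
#' @param geometric geometric metric values (e.g. dsc).
#' @param abs_percent absolute percent dose changes.
#' @return one-row data.frame: r, n, p, available.
#' @export
pearson_correlation <- function(geometric, abs_percent) {
  keep <- stats::complete.cases(geometric, abs_percent)
  x <- as.numeric(geometric[keep]); y <- as.numeric(abs_percent[keep])
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(r = NA_real_, n = n, p = NA_real_, available = FALSE,
                      stringsAsFactors = FALSE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  r <- max(min(r, 1), -1)
  p <- if (n >= 3 && abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), n - 2)
  } else NA_real_
  data.frame(r = r, n = n, p = p, available = TRUE, stringsAsFactors = FALSE)
}

#' Geometric-dosimetric correlation table
#'
#' One Pearson r per model per geometric metric (dsc, sensitivity,
#' mean_dta_mm) against absolute percent dose change, pooled across organs
#' and cases.
#'
#' @param per_case table with model, dsc, sensitivity, mean_dta_mm,
#'   abs_percent, status.
#' @return data.frame: model, metric, r, n, p, available.
#' @export
correlate_geometry_dose <- function(per_case) {
  needed <- c("model", "dsc", "sensitivity", "mean_dta_mm", "abs_percent")
  if (!all(needed %in% names(per_case)))
    stop("per_case table lacks columns: ",
         paste(setdiff(needed, names(per_case)), collapse = ", "))
  rows <- list()
  for (model in sort(unique(per_case$model))) {
    sub <- per_case[per_case$model == model, ]
    for (metric in c("dsc", "sensitivity", "mean_dta_mm")) {
      res <- pearson_correlation(sub[[metric]], sub$abs_percent)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(model = model, metric = metric, stringsAsFactors = FALSE),
        res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
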