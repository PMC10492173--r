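#' Flag observations for reprocessing
#'
#' Flags every observation marked uncertain plus every observation whose
#' absolute z score against its own test's mean and SD (over all current
#' values) exceeds `z`. With fewer than two values, or zero spread, only
#' uncertainty flags apply.
#'
#' @param observations Observation data frame (columns `test`, `value`,
#'   `uncertain`).
#' @param z Reprocessing threshold (default 2).
#' @return The flagged subset of `observations`, with a `flag_reason`
#'   column (`"uncertain"`, `"zscore"`, or `"uncertain+zscore"`).
#' @export
flag_reprocess <- function(observations, z = 2) {
  if (!nrow(observations)) {
    out <- observations
    out$flag_reason <- character(0)
    return(out)
  }
  zs <- rep(0, nrow(observations))
  for (id in unique(observations$test)) {
    ix <- which(observations$test == id)
    v <- observations$value[ix]
    if (length(v) >= 2) {
      s <- stats::sd(v)
      if (is.finite(s) && s > 0) zs[ix] <- abs((v - mean(v)) / s)
    }
  }
  zflag <- zs > z
  uflag <- isTRUE_vec(observations$uncertain)
  keep <- zflag | uflag
  out <- observations[keep, , drop = FALSE]
  out$flag_reason <- ifelse(zflag[keep] & uflag[keep], "uncertain+zscore",
                            ifelse(uflag[keep], "uncertain", "zscore"))
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Remove extreme outliers by z score
#'
#' Single pass: z scores are computed against the pre-removal mean and SD,
#' and every value with |z| > `zmax` is removed. Zero spread removes
#' nothing. The removal rate is reported per call.
#'
#' @param values Numeric vector (>= 2 values for z scoring).
#' @param zmax Removal threshold (the pipeline default of 4 deliberately
#'   allows more outliers than the conventional 2 or 3, since dysregulated
#'   cohorts are expected to produce extreme but genuine values).
#' @return List with `kept`, `removed` (values), `kept_idx`, `removed_idx`
#'   (indices into the input), and `rate` (percent removed).
#' @export
remove_outliers <- function(values, zmax = 4) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 2) {
    return(list(kept = values, removed = numeric(0),
                kept_idx = seq_len(n), removed_idx = integer(0), rate = 0))
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(kept = values, removed = numeric(0),
                kept_idx = seq_len(n), removed_idx = integer(0), rate = 0))
  }
  z <- abs((values - mean(values)) / s)
  out <- z > zmax
  list(kept = values[!out], removed = values[out],
       kept_idx = which(!out), removed_idx = which(out),
       rate = 100 * sum(out) / n)
}

#' Summarize a cohort of test sets
#'
#' One row per test with at least `min_count` post-removal observations:
#' count, percent of test sets containing the result, mean, SD, median,
#' quartiles, observed extremes, percent uncertain (pre-removal), and
#' percent of values removed as outliers.
#'
#' @param assembled Result of [assemble_test_sets()] (optionally after
#'   [compute_derived()]).
#' @param min_count Minimum post-removal observation count for a row.
#' @param zmax Outlier-removal threshold passed to [remove_outliers()].
#' @return A `cohort_table` data frame.
#' @export
summarize_cohort <- function(assembled, min_count = 20, zmax = 4) {
  obs <- assembled$observations
  n_sets <- nrow(assembled$sets)
  rows <- list()
  for (id in unique(obs$test)) {
    sub <- obs[obs$test == id, , drop = FALSE]
    rem <- remove_outliers(sub$value, zmax)
    v <- rem$kept
    if (length(v) < min_count) next
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    kept_sets <- unique(sub$set_id[rem$kept_idx])
    rows[[id]] <- data.frame(
      test = id, n = length(v),
      pct_sets = if (n_sets > 0) 100 * length(kept_sets) / n_sets else 0,
      mean = mean(v), sd = stats::sd(v), median = q[2], q1 = q[1], q3 = q[3],
      min = min(v), max = max(v),
      pct_uncertain = 100 * mean(isTRUE_vec(sub$uncertain)),
      pct_outliers = rem$rate, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(test = character(0), n = integer(0), pct_sets = numeric(0),
               mean = numeric(0), sd = numeric(0), median = numeric(0),
               q1 = numeric(0), q3 = numeric(0), min = numeric(0),
               max = numeric(0), pct_uncertain = numeric(0),
               pct_outliers = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", class(out))
  out
}

#' Run the full quality-control stage
#'
#' Applies the reprocessing rule (uncertain values are re-run through
#' [infer_unit()] once with widened plausibility), removes extreme
#' outliers per test, and produces the cohort summary plus a QC report.
#'
#' @param assembled Result of [assemble_test_sets()]/[compute_derived()].
#' @param catalog A `lab_catalog` (for reprocessing).
#' @param z_reprocess,zmax,min_count QC thresholds.
#' @param widen Plausibility widening used on the reprocessing pass.
#' @return List with `summary` (cohort table), `report` (per-test QC
#'   counts), and `assembled` (observations after reprocessing).
#' @export
qc_cohort <- function(assembled, catalog = lab_catalog(),
                      z_reprocess = 2, zmax = 4, min_count = 20,
                      widen = 1.5) {
  obs <- assembled$observations
  flagged <- flag_reprocess(obs, z = z_reprocess)
  # reprocess uncertain raw mentions once with widened plausibility
  if (nrow(flagged)) {
    for (i in seq_len(nrow(flagged))) {
      if (!grepl("uncertain", flagged$flag_reason[i])) next
      key <- which(obs$post_id == flagged$post_id[i] &
                     obs$test == flagged$test[i] &
                     obs$date == flagged$date[i])
      for (k in key) {
        if (!is.finite(obs$raw_value[k])) next
        r <- infer_unit(obs$test[k], obs$raw_value[k], obs$raw_unit[k],
                        catalog, widen = widen)
        if (!r$rejected) {
          obs$value[k] <- r$value
          obs$uncertain[k] <- r$uncertain
        }
      }
    }
  }
  assembled$observations <- obs
  report <- list()
  for (id in unique(obs$test)) {
    sub <- obs[obs$test == id, , drop = FALSE]
    rem <- remove_outliers(sub$value, zmax)
    fl <- flag_reprocess(sub, z = z_reprocess)
    report[[id]] <- data.frame(
      test = id, n = nrow(sub), n_reprocess = nrow(fl),
      n_removed = length(rem$removed_idx), outlier_rate = rem$rate,
      uncertainty_rate = 100 * mean(isTRUE_vec(sub$uncertain)),
      stringsAsFactors = FALSE)
  }
  report_df <- if (length(report)) {
    do.call(rbind, c(report, list(make.row.names = FALSE)))
  } else {
    data.frame(test = character(0), n = integer(0), n_reprocess = integer(0),
               n_removed = integer(0), outlier_rate = numeric(0),
               uncertainty_rate = numeric(0), stringsAsFactors = FALSE)
  }
  list(summary = summarize_cohort(assembled, min_count, zmax),
       report = report_df, assembled = assembled)
}

#' Render a cohort table the way clinical summaries print it
#'
#' Means as "mean (SD)" and the central column as "median (min-max)",
#' matching the convention of printing observed extremes in the
#' parenthesis.
#'
#' @param x A `cohort_table`.
#' @return Data frame of formatted strings.
#' @export
format_cohort_table <- function(x) {
  data.frame(
    test = x$test, n = x$n,
    pct_sets = sprintf("%.1f", x$pct_sets),
    mean_sd = sprintf("%.1f (%.1f)", x$mean, x$sd),
    median_range = sprintf("%.1f (%.4g-%.4g)", x$median, x$min, x$max),
    pct_uncertain = sprintf("%.1f", x$pct_uncertain),
    pct_outliers = sprintf("%.1f", x$pct_outliers),
    stringsAsFactors = FALSE)
}
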