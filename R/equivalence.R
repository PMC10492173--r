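#' Load the packaged literature cohort fixture
#'
#' Transcribed summary statistics (per-study PCOS group size, and per-test
#' mean and SD in the canonical units of the catalog) for the ten published
#' PCOS cohorts used in comparisons, plus the printed aggregate table.
#'
#' @return `literature_studies()`: data frame `study`, `test`, `n`, `mean`,
#'   `sd`, `unit`, `code` (printed comparison annotation: a = equivalent,
#'   b = literature lower, c = literature higher), with study context
#'   (cycle phase, fasting status) attached as attribute `cohorts`.
#' @export
literature_studies <- function() {
  vals <- utils::read.csv(system.file("extdata", "literature_values.csv",
                                      package = "forumlabs"),
                          stringsAsFactors = FALSE)
  coh <- utils::read.csv(system.file("extdata", "literature_cohorts.csv",
                                     package = "forumlabs"),
                         stringsAsFactors = FALSE)
  vals$n <- coh$n[match(vals$study, coh$study)]
  attr(vals, "cohorts") <- coh
  vals
}

#' @rdname literature_studies
#' @return `literature_aggregate()`: the printed aggregate rows (`test`,
#'   `n`, `mean`, `sd`, `unit`, `verdict`).
#' @export
literature_aggregate <- function() {
  utils::read.csv(system.file("extdata", "literature_aggregate.csv",
                              package = "forumlabs"),
                  stringsAsFactors = FALSE)
}

#' @rdname literature_studies
#' @return `subreddit_summary()`: the forum-cohort summary table used as
#'   the subreddit side of printed-input comparisons and as the default
#'   generator parameters.
#' @export
subreddit_summary <- function() {
  utils::read.csv(system.file("extdata", "subreddit_summary.csv",
                              package = "forumlabs"),
                  stringsAsFactors = FALSE)
}

#' Aggregate literature means for one test
#'
#' Sample-size-weighted mean over the studies reporting the test:
#' n = sum of n_i, mean = sum(n_i m_i) / sum(n_i).
#'
#' @param studies Data frame with columns `study`, `test`, `n`, `mean`, `sd`.
#' @param test Test id.
#' @return List `n`, `mean`, and `pooled_sd` (degrees-of-freedom-weighted;
#'   reported separately because it is not the quantity printed in the
#'   aggregate table).
#' @export
aggregate_mean <- function(studies, test) {
  s <- studies[studies$test == test, , drop = FALSE]
  if (!nrow(s)) stop("no study reports test '", test, "'", call. = FALSE)
  n <- sum(s$n)
  list(n = n, mean = sum(s$n * s$mean) / n,
       pooled_sd = pooled_sd(s$n, s$sd))
}

#' Pooled standard deviation
#'
#' sqrt( sum (n_i - 1) SD_i^2 / sum (n_i - 1) ), over two or more groups.
#'
#' @param n Group sizes (each >= 2).
#' @param sd Group standard deviations.
#' @return The pooled SD.
#' @export
pooled_sd <- function(n, sd) {
  stopifnot(length(n) == length(sd), length(n) >= 1)
  if (any(n < 2)) stop("pooled SD requires every group size >= 2", call. = FALSE)
  sqrt(sum((n - 1) * sd^2) / sum(n - 1))
}

#' Equivalence boundary specification
#'
#' The boundary is b = d x SD_pooled with d a medium Cohen effect (0.499),
#' and alpha the significance level for both the TOST and the directional
#' fallback.
#'
#' @param d Cohen-d multiplier (> 0).
#' @param alpha Significance level in (0, 1).
#' @param welch Use Welch (unequal-variance) standard errors and degrees of
#'   freedom instead of the pooled-variance default. The boundary itself is
#'   always built from the pooled SD.
#' @return A `boundary_spec` list.
#' @export
boundary_spec <- function(d = 0.499, alpha = 0.05, welch = FALSE) {
  stopifnot(d > 0, alpha > 0, alpha < 1)
  structure(list(d = d, alpha = alpha, welch = welch), class = "boundary_spec")
}

t_error <- function(sdA, nA, sdB, nB, welch) {
  sp <- pooled_sd(c(nA, nB), c(sdA, sdB))
  if (welch) {
    se <- sqrt(sdA^2 / nA + sdB^2 / nB)
    df <- (sdA^2 / nA + sdB^2 / nB)^2 /
      ((sdA^2 / nA)^2 / (nA - 1) + (sdB^2 / nB)^2 / (nB - 1))
  } else {
    se <- sp * sqrt(1 / nA + 1 / nB)
    df <- nA + nB - 2
  }
  list(sp = sp, se = se, df = df)
}

#' Two one-sided t tests (TOST) for equivalence from summary statistics
#'
#' Tests the null that |meanA - meanB| >= b against equivalence, with
#' b = d x pooled SD of the two groups. The reported p is the larger of the
#' two one-sided p values; equivalence is concluded when p < alpha.
#'
#' @param meanA,sdA,nA Group A summary (nA >= 2).
#' @param meanB,sdB,nB Group B summary (nB >= 2).
#' @param spec A [boundary_spec()].
#' @return List: `b` (boundary), `p`, `equivalent`, `se`, `df`,
#'   `p_lower`, `p_upper`, `delta`.
#' @export
tost <- function(meanA, sdA, nA, meanB, sdB, nB, spec = boundary_spec()) {
  stopifnot(nA >= 2, nB >= 2, sdA >= 0, sdB >= 0)
  if (sdA == 0 && sdB == 0) stop("both SDs are zero", call. = FALSE)
  err <- t_error(sdA, nA, sdB, nB, spec$welch)
  b <- spec$d * err$sp
  delta <- meanA - meanB
  if (b <= 0) {
    return(list(b = b, p = 1, equivalent = FALSE, se = err$se, df = err$df,
                p_lower = 1, p_upper = 1, delta = delta, degenerate = TRUE))
  }
  p_lower <- stats::pt((delta + b) / err$se, err$df, lower.tail = FALSE)
  p_upper <- stats::pt((delta - b) / err$se, err$df)
  p <- max(p_lower, p_upper)
  list(b = b, p = p, equivalent = p < spec$alpha, se = err$se, df = err$df,
       p_lower = p_lower, p_upper = p_upper, delta = delta, degenerate = FALSE)
}

#' One-sided directional t test from summary statistics
#'
#' Invoked when equivalence is not concluded: decides whether group B's
#' mean is statistically lower or higher than group A's.
#'
#' @inheritParams tost
#' @param spec A [boundary_spec()]; `alpha` and the error model are used.
#' @return List: `direction` (`"B-lower"`, `"B-higher"`, or `"none"`) and
#'   `p` (the smaller one-sided p value).
#' @export
directional_test <- function(meanA, sdA, nA, meanB, sdB, nB,
                             spec = boundary_spec()) {
  stopifnot(nA >= 2, nB >= 2, sdA >= 0, sdB >= 0)
  if (sdA == 0 && sdB == 0) stop("both SDs are zero", call. = FALSE)
  err <- t_error(sdA, nA, sdB, nB, spec$welch)
  t <- (meanA - meanB) / err$se
  p_b_lower <- stats::pt(t, err$df, lower.tail = FALSE)
  p_b_higher <- stats::pt(t, err$df)
  if (p_b_lower < spec$alpha) list(direction = "B-lower", p = p_b_lower)
  else if (p_b_higher < spec$alpha) list(direction = "B-higher", p = p_b_higher)
  else list(direction = "none", p = min(p_b_lower, p_b_higher))
}

#' Compare two summarized groups: equivalence first, direction as fallback
#'
#' @inheritParams tost
#' @return One-row data frame with the boundary, both p values, and a
#'   `verdict` in `{equivalent, literature-lower, literature-higher,
#'   inconclusive}` (group B is the literature side), plus code a/b/c.
#' @export
compare_groups <- function(meanA, sdA, nA, meanB, sdB, nB,
                           spec = boundary_spec()) {
  tt <- tost(meanA, sdA, nA, meanB, sdB, nB, spec)
  if (tt$equivalent) {
    verdict <- "equivalent"; code <- "a"; p_dir <- NA_real_
  } else {
    dd <- directional_test(meanA, sdA, nA, meanB, sdB, nB, spec)
    p_dir <- dd$p
    verdict <- switch(dd$direction,
                      "B-lower" = "literature-lower",
                      "B-higher" = "literature-higher",
                      "none" = "inconclusive")
    code <- switch(dd$direction, "B-lower" = "b", "B-higher" = "c",
                   "none" = "-")
  }
  data.frame(n_a = nA, mean_a = meanA, sd_a = sdA,
             n_b = nB, mean_b = meanB, sd_b = sdB,
             pooled_sd = pooled_sd(c(nA, nB), c(sdA, sdB)),
             boundary = tt$b, p_tost = tt$p, p_directional = p_dir,
             verdict = verdict, code = code, stringsAsFactors = FALSE)
}

#' Build the aggregate and per-study comparison matrices
#'
#' For every test present on both sides: one comparison against the
#' aggregate literature summary, and one per (test, study) cell where the
#' study reports the test. Units must agree between sides before any test
#' runs.
#'
#' @param subreddit Cohort summary rows for the forum side (columns `test`,
#'   `n`, `mean`, `sd`, optionally `unit`).
#' @param studies Per-study literature data frame (see
#'   [literature_studies()]).
#' @param aggregate Optional printed aggregate table. When supplied, its
#'   n/mean/SD are used as the aggregate comparison inputs; the computed
#'   n-weighted mean and pooled SD are still reported alongside. When
#'   omitted, computed aggregates are used.
#' @param spec A [boundary_spec()].
#' @param catalog A `lab_catalog` used to check unit agreement.
#' @return List with `aggregate` and `per_study` comparison data frames.
#' @export
compare_matrix <- function(subreddit, studies, aggregate = NULL,
                           spec = boundary_spec(), catalog = lab_catalog()) {
  tests <- intersect(subreddit$test, unique(studies$test))
  check_units <- function(tbl, label) {
    if (is.null(tbl$unit)) return(invisible())
    for (id in intersect(tbl$test, names(catalog))) {
      u <- unique(tbl$unit[tbl$test == id])
      u <- u[!is.na(u)]
      bad <- u[nzchar(u) & normalize_unit(u) != normalize_unit(catalog[[id]]$unit)]
      if (length(bad)) {
        stop(label, " reports ", id, " in '", bad[1], "' but the canonical unit is '",
             catalog[[id]]$unit, "'", call. = FALSE)
      }
    }
  }
  check_units(subreddit, "forum summary")
  check_units(studies, "literature fixture")
  if (!is.null(aggregate)) check_units(aggregate, "aggregate table")

  agg_rows <- list()
  cell_rows <- list()
  for (id in tests) {
    srow <- subreddit[subreddit$test == id, ][1, ]
    agg_calc <- aggregate_mean(studies, id)
    if (!is.null(aggregate) && id %in% aggregate$test) {
      arow <- aggregate[aggregate$test == id, ][1, ]
      cmp <- compare_groups(srow$mean, srow$sd, srow$n,
                            arow$mean, arow$sd, arow$n, spec)
    } else {
      cmp <- compare_groups(srow$mean, srow$sd, srow$n,
                            agg_calc$mean, agg_calc$pooled_sd, agg_calc$n, spec)
    }
    cmp <- cbind(data.frame(test = id, stringsAsFactors = FALSE), cmp)
    cmp$agg_n_calc <- agg_calc$n
    cmp$agg_mean_calc <- agg_calc$mean
    cmp$agg_pooled_sd_calc <- agg_calc$pooled_sd
    agg_rows[[id]] <- cmp
    per <- studies[studies$test == id, , drop = FALSE]
    for (k in seq_len(nrow(per))) {
      cell <- compare_groups(srow$mean, srow$sd, srow$n,
                             per$mean[k], per$sd[k], per$n[k], spec)
      cell <- cbind(data.frame(test = id, study = per$study[k],
                               stringsAsFactors = FALSE), cell)
      cell_rows[[paste(id, per$study[k])]] <- cell
    }
  }
  empty_cmp <- function(extra) {
    base <- compare_groups(1, 1, 2, 1, 1, 2)[0, ]
    cbind(extra, base)
  }
  list(aggregate = if (length(agg_rows))
    do.call(rbind, c(agg_rows, list(make.row.names = FALSE))) else
      empty_cmp(data.frame(test = character(0))),
    per_study = if (length(cell_rows))
      do.call(rbind, c(cell_rows, list(make.row.names = FALSE))) else
        empty_cmp(data.frame(test = character(0), study = character(0))))
}
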