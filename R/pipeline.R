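#' Read forum posts from JSON Lines
#'
#' One JSON object per line in the public Reddit archive dialect (keys
#' `id`, `author`, `created_utc`, `title`, `selftext`). Extra keys are
#' ignored; a missing title or body becomes the empty string; malformed
#' lines are counted and reported via a warning, and more than 10%
#' malformed lines is an error.
#'
#' @param path Path to a JSONL file.
#' @return Post data frame with attribute `n_malformed`.
#' @export
load_posts <- function(path) {
  if (!file.exists(path)) stop("cannot read posts file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  bad <- 0L
  incomplete <- 0L
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(obj) || is.null(obj$id)) {
      bad <- bad + 1L
      next
    }
    if (is.null(obj$title) || is.null(obj$selftext)) incomplete <- incomplete + 1L
    g <- function(key, default) {
      v <- obj[[key]]
      if (is.null(v) || !length(v)) default else v
    }
    rows[[i]] <- data.frame(
      id = as.character(obj$id),
      author = as.character(g("author", "[unknown]")),
      created_utc = as.numeric(g("created_utc", 0)),
      title = as.character(g("title", "")),
      selftext = as.character(g("selftext", "")),
      stringsAsFactors = FALSE)
  }
  if (length(lines) && bad / length(lines) > 0.1) {
    stop(sprintf("%d of %d lines malformed (>10%%)", bad, length(lines)),
         call. = FALSE)
  }
  if (bad > 0) warning(bad, " malformed line(s) skipped")
  if (incomplete > 0) {
    warning(incomplete, " post(s) missing title or selftext; treated as empty")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(id = character(0), author = character(0),
                      created_utc = numeric(0), title = character(0),
                      selftext = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "n_malformed") <- bad
  out
}

#' Write a table of results as delimited text
#'
#' @param rows Data frame.
#' @param path Output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param digits Optional named integer vector giving decimal places per
#'   numeric column (counts are left untouched).
#' @return The path, invisibly.
#' @export
write_table <- function(rows, path, dialect = c("tsv", "csv"), digits = NULL) {
  dialect <- match.arg(dialect)
  if (!is.null(digits)) {
    for (nm in intersect(names(digits), names(rows))) {
      rows[[nm]] <- formatC(rows[[nm]], format = "f", digits = digits[[nm]])
    }
  }
  utils::write.table(rows, path, sep = if (dialect == "tsv") "\t" else ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed Master seed for every stage.
#' @param n_posts Synthetic corpus size.
#' @param n_labeled Posts labeled (from generator truth) to train the
#'   screen, echoing the scale of a few hundred manually labeled posts.
#' @param classifier `"cnn"` or `"rule"`.
#' @param embedding_dim,embedding_iters GloVe hyperparameters.
#' @param threshold Screen decision threshold.
#' @param ambiguity Unit-inference ambiguity threshold.
#' @param z_reprocess,zmax,min_count QC thresholds.
#' @param d,alpha Equivalence boundary parameters.
#' @param out_dir Output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_posts = 2000, n_labeled = 300,
                            classifier = c("cnn", "rule"),
                            embedding_dim = 50, embedding_iters = 60,
                            threshold = 0.5, ambiguity = 0.2,
                            z_reprocess = 2, zmax = 4, min_count = 20,
                            d = 0.499, alpha = 0.05,
                            out_dir = tempfile("forumlabs_run_")) {
  classifier <- match.arg(classifier)
  stopifnot(z_reprocess > 0, zmax > 0, min_count > 0, threshold > 0,
            threshold < 1)
  structure(list(seed = as.integer(seed), n_posts = n_posts,
                 n_labeled = n_labeled, classifier = classifier,
                 embedding_dim = embedding_dim,
                 embedding_iters = embedding_iters,
                 threshold = threshold, ambiguity = ambiguity,
                 z_reprocess = z_reprocess, zmax = zmax,
                 min_count = min_count, d = d, alpha = alpha,
                 out_dir = out_dir), class = "pipeline_config")
}

log_stage <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' generate -> screen -> extract -> assemble/QC -> compare. Every stage is
#' seeded from the configuration, and a manifest with the seed,
#' configuration, and stage-by-stage counts (the processing funnel) is
#' written alongside the tables. With `corpus = FALSE` the corpus stages
#' are skipped and only the literature-comparison tables are produced from
#' the packaged printed inputs.
#'
#' @param config A [pipeline_config()].
#' @param corpus Generate and process a synthetic corpus (default) or run
#'   the printed-tables reproduction mode only.
#' @return Invisibly, a list with the main artifacts (`summary`,
#'   `comparisons`, `manifest`, paths).
#' @export
run_pipeline <- function(config = pipeline_config(), corpus = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  catalog <- lab_catalog()
  manifest <- list(seed = config$seed,
                   config = unclass(config),
                   counts = list())
  results <- list()

  if (corpus) {
    spec <- default_panel_spec(catalog)
    log_stage(con, "simulate", sprintf("generating %d posts (seed %d)",
                                       config$n_posts, config$seed))
    corp <- generate_corpus(spec, n_posts = config$n_posts, seed = config$seed)
    write_posts(corp$posts, file.path(config$out_dir, "posts.jsonl"))
    write_truth(corp$truth, file.path(config$out_dir, "truth.json"))
    manifest$counts$posts <- nrow(corp$posts)

    log_stage(con, "screen", sprintf("training %s classifier", config$classifier))
    labels <- vapply(corp$truth, `[[`, logical(1), "contains_results")
    if (config$classifier == "cnn") {
      tok_all <- lapply(paste(corp$posts$title, corp$posts$selftext), preprocess)
      emb <- train_embeddings(tok_all, d = config$embedding_dim,
                              iters = config$embedding_iters,
                              seed = config$seed)
      set.seed(config$seed + 1L)
      lab_ix <- sample(nrow(corp$posts), min(config$n_labeled, nrow(corp$posts)))
      labeled <- data.frame(label = labels[corp$posts$id[lab_ix]])
      labeled$tokens <- tok_all[lab_ix]
      model <- train_screen(labeled, emb,
                            hyper = list(threshold = config$threshold),
                            seed = config$seed)
      metrics <- evaluate_screen(model)
    } else {
      model <- rule_screen(catalog, threshold = config$threshold)
      metrics <- if (nrow(corp$posts)) {
        evaluate_screen(model, data.frame(
          text = paste(corp$posts$title, corp$posts$selftext),
          label = as.integer(labels[corp$posts$id]),
          stringsAsFactors = FALSE))
      } else {
        list(accuracy = NA_real_, tp = 0L, fp = 0L, tn = 0L, fn = 0L)
      }
    }
    scr <- screen(model, corp$posts)
    write_table(data.frame(metric = c("accuracy", "tp", "fp", "tn", "fn"),
                           value = unlist(metrics)),
                file.path(config$out_dir, "screen_metrics.tsv"))
    manifest$counts$flagged <- sum(scr$flag)
    log_stage(con, "screen", sprintf("flagged %d of %d posts (held-out accuracy %.3f)",
                                     sum(scr$flag), nrow(corp$posts),
                                     metrics$accuracy))

    flagged_posts <- corp$posts[scr$flag, , drop = FALSE]
    ext <- extract_observations(flagged_posts, catalog,
                                ambiguity = config$ambiguity)
    manifest$counts$posts_with_mentions <- length(unique(ext$observations$post_id))
    manifest$counts$observations <- nrow(ext$observations)
    manifest$counts$rejections <- nrow(ext$rejections)
    log_stage(con, "extract", sprintf("%d observations, %d rejections",
                                      nrow(ext$observations), nrow(ext$rejections)))
    write_table(ext$rejections, file.path(config$out_dir, "rejections.tsv"))

    asm <- compute_derived(assemble_test_sets(ext$observations))
    manifest$counts$observations_deduped <- nrow(asm$observations)
    manifest$counts$test_sets <- nrow(asm$sets)
    qc <- qc_cohort(asm, catalog, z_reprocess = config$z_reprocess,
                    zmax = config$zmax, min_count = config$min_count)
    manifest$counts$observations_kept <-
      sum(qc$report$n) - sum(qc$report$n_removed)
    log_stage(con, "qc", sprintf("%d test sets; %d observation(s) removed as outliers",
                                 nrow(asm$sets), sum(qc$report$n_removed)))
    write_table(qc$report, file.path(config$out_dir, "qc_report.tsv"))
    write_table(format_cohort_table(qc$summary),
                file.path(config$out_dir, "table3_cohort.tsv"))
    results$summary <- qc$summary
    results$screen_metrics <- metrics
    results$truth <- corp$truth
    subreddit_side <- qc$summary
  } else {
    subreddit_side <- subreddit_summary()
  }

  log_stage(con, "compare", "running TOST comparisons against literature")
  spec_b <- boundary_spec(d = config$d, alpha = config$alpha)
  studies <- literature_studies()
  agg <- literature_aggregate()
  # corpus mode compares the synthetic cohort, whose units are canonical by
  # construction; printed mode uses the packaged forum summary
  cmp <- compare_matrix(subreddit_side, studies,
                        aggregate = if (corpus) NULL else agg,
                        spec = spec_b, catalog = catalog)
  write_table(cmp$aggregate, file.path(config$out_dir, "table4_aggregate.tsv"),
              digits = c(mean_b = 1, sd_b = 1, boundary = 2))
  write_table(cmp$per_study, file.path(config$out_dir, "table5_per_study.tsv"),
              digits = c(mean_b = 1, sd_b = 1, boundary = 2))
  results$comparisons <- cmp

  manifest$counts$comparisons_aggregate <- nrow(cmp$aggregate)
  manifest$counts$comparisons_per_study <- nrow(cmp$per_study)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  results$out_dir <- config$out_dir
  log_stage(con, "done", config$out_dir)
  invisible(results)
}
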