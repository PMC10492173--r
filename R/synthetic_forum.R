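#' Build a laboratory panel specification for the synthetic forum
#'
#' Combines the test catalog with a cohort summary table (per-test mean, SD,
#' and the fraction of test sets reporting the test) into the generative
#' specification used by [sample_cohort()] and [generate_corpus()]. Each
#' entry records the latent distribution family (normal or lognormal,
#' truncated to the condition-plausible range), its location and scale in
#' canonical units, and the probability that a synthetic post reports the
#' test.
#'
#' @param catalog A `lab_catalog`.
#' @param summary_path CSV with columns `test`, `mean`, `sd`, `pct_sets`.
#'   Defaults to the packaged forum-cohort summary.
#' @return An object of class `panel_spec`.
#' @export
default_panel_spec <- function(catalog = lab_catalog(), summary_path = NULL) {
  if (is.null(summary_path)) {
    summary_path <- system.file("extdata", "subreddit_summary.csv", package = "forumlabs")
  }
  s <- utils::read.csv(summary_path, stringsAsFactors = FALSE)
  entries <- list()
  for (i in seq_len(nrow(s))) {
    id <- s$test[i]
    t <- catalog[[id]]
    if (is.null(t)) next
    entries[[id]] <- list(
      family = t$family, location = s$mean[i], scale = s$sd[i],
      prevalence = s$pct_sets[i] / 100, unit = t$unit, alt_units = t$alt_units,
      plausible = t$plausible, healthy = t$healthy, digits = t$digits,
      name = t$name, synonyms = t$synonyms
    )
  }
  validate_panel_spec(entries)
  structure(entries, class = "panel_spec")
}

validate_panel_spec <- function(entries) {
  for (id in names(entries)) {
    e <- entries[[id]]
    if (!is.finite(e$scale) || e$scale <= 0) {
      stop("panel spec '", id, "': scale must be positive", call. = FALSE)
    }
    if (e$prevalence < 0 || e$prevalence > 1) {
      stop("panel spec '", id, "': prevalence must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Inverse-CDF draw from a normal or lognormal truncated to [lo, hi].
rtrunc <- function(n, family, location, scale, lo, hi) {
  if (family == "lognormal") {
    sig2 <- log(1 + (scale / location)^2)
    mu <- log(location) - sig2 / 2
    sig <- sqrt(sig2)
    plo <- stats::plnorm(max(lo, 0), mu, sig)
    phi <- stats::plnorm(hi, mu, sig)
    stats::qlnorm(stats::runif(n, plo, phi), mu, sig)
  } else {
    plo <- stats::pnorm(lo, location, scale)
    phi <- stats::pnorm(hi, location, scale)
    stats::qnorm(stats::runif(n, plo, phi), location, scale)
  }
}

sample_person <- function(spec, index) {
  draw1 <- function(e) rtrunc(1, e$family, e$location, e$scale, e$plausible[1], e$plausible[2])
  panel <- numeric(0)
  analytes <- names(spec)
  repeat {
    include <- stats::runif(length(analytes)) < vapply(spec, `[[`, numeric(1), "prevalence")
    if (any(include[!analytes %in% c("age", "bmi")])) break
  }
  for (id in analytes[include]) panel[id] <- draw1(spec[[id]])
  age <- if ("age" %in% names(panel)) panel[["age"]] else draw1(spec[["age"]])
  bmi <- if ("bmi" %in% names(panel)) panel[["bmi"]] else draw1(spec[["bmi"]])
  list(account = sprintf("user_%05d", index), age = age, bmi = bmi,
       panel = panel, n_days = 1L)
}

#' Sample a synthetic cohort of forum participants
#'
#' Each person carries a latent laboratory panel: one true value per included
#' test, drawn from the panel specification's distribution (truncated to the
#' catalog's condition-plausible range) with tests included independently
#' according to their prevalence. Every person has a latent age and BMI.
#'
#' @param spec A `panel_spec`.
#' @param n_persons Number of people to generate (>= 1).
#' @param seed Integer seed; the same call with the same seed reproduces the
#'   cohort exactly.
#' @return A list of persons, each a list with `account`, `age`, `bmi`,
#'   `panel` (named numeric, canonical units), `n_days`.
#' @export
sample_cohort <- function(spec, n_persons, seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"), n_persons >= 1)
  validate_panel_spec(spec)
  set.seed(seed)
  lapply(seq_len(n_persons), function(i) sample_person(spec, i))
}

forum_styles <- function() {
  c("full-name-with-unit", "abbreviation-with-unit", "no-unit",
    "alternate-unit", "mistyped-unit", "split-pair", "duplicate-repost",
    "distractor")
}

fmt_val <- function(v, digits) formatC(round(v, digits), format = "f", digits = digits)

# Decimal places needed to render in an alternate unit so the round trip
# stays within half an ulp of the canonical rendering precision.
alt_digits <- function(digits, factor) max(0L, as.integer(ceiling(digits + log10(factor))))

unit_display <- function(unit) {
  variants <- c(unit, tolower(unit))
  variants[sample.int(length(variants), 1)]
}

# Render one laboratory mention. Returns the text fragment plus the ground
# truth record (true canonical value, number and unit as written, tolerance
# implied by the rendered precision).
render_mention <- function(id, e, value, style) {
  syn_short <- e$synonyms[which.min(nchar(e$synonyms))]
  syn <- if (style == "full-name-with-unit") e$name else {
    e$synonyms[sample.int(length(e$synonyms), 1)]
  }
  unit_txt <- ""
  rendered <- fmt_val(value, e$digits)
  tol <- 0.5 * 10^(-e$digits)
  actual_style <- style
  if (style %in% c("full-name-with-unit", "abbreviation-with-unit")) {
    unit_txt <- if (nzchar(e$unit)) unit_display(e$unit) else ""
  } else if (style == "no-unit") {
    syn <- syn_short
  } else if (style == "alternate-unit") {
    if (length(e$alt_units)) {
      k <- sample.int(length(e$alt_units), 1)
      fac <- e$alt_units[[k]]
      d <- alt_digits(e$digits, fac)
      rendered <- fmt_val(value / fac, d)
      tol <- 0.5 * 10^(-d) * fac
      unit_txt <- unit_display(names(e$alt_units)[k])
    } else {
      unit_txt <- if (nzchar(e$unit)) unit_display(e$unit) else ""
      actual_style <- "abbreviation-with-unit"
    }
  } else if (style == "mistyped-unit") {
    # keep the number, swap the unit label. Only done when every
    # non-canonical reading of the number is implausible, so that the
    # mistranscription check recovers the true value unambiguously.
    units_all <- c(e$unit, names(e$alt_units))
    facs <- c(1, unname(e$alt_units))
    v_num <- as.numeric(rendered)
    implaus <- v_num * facs < e$plausible[1] | v_num * facs > e$plausible[2]
    ok <- which(nzchar(units_all) & facs != 1 & implaus)
    if (length(ok) && all(implaus[facs != 1])) {
      k <- ok[sample.int(length(ok), 1)]
      unit_txt <- unit_display(units_all[k])
    } else {
      unit_txt <- if (nzchar(e$unit)) unit_display(e$unit) else ""
      actual_style <- "abbreviation-with-unit"
    }
  }
  templates <- c("My %s was %s%s.", "%s: %s%s", "%s came back at %s%s.",
                 "%s %s%s")
  tpl <- templates[sample.int(length(templates), 1)]
  u <- if (nzchar(unit_txt)) paste0(" ", unit_txt) else ""
  list(text = sprintf(tpl, syn, rendered, u),
       truth = data.frame(test = id, value = value, rendered = rendered,
                          unit = unit_txt, style = actual_style, tol = tol,
                          stringsAsFactors = FALSE))
}

distractor_text <- function() {
  pool <- c(
    "Has anyone tried inositol for their symptoms? Wondering if it helped.",
    "Feeling really frustrated with my doctor today, she barely listened.",
    "Been on metformin for a while now and the side effects are rough.",
    "Anyone else struggle with hair growth on their chin? Looking for tips.",
    "Just got diagnosed and I have no idea where to start. Any advice?",
    "My periods have been irregular for years and nobody took it seriously.",
    "Started spearmint tea last month, fingers crossed it does something.",
    "Looking for a new gynecologist who actually knows about this condition.",
    "The waiting list for the endocrinologist is three months long, ugh.",
    "Does anyone have recipes that helped with cravings? Struggling lately.",
    "Should I ask for testosterone and insulin panels at my next visit?",
    "My ultrasound is scheduled for next week and I am so nervous."
  )
  pool[sample.int(length(pool), 1)]
}

post_titles <- function() {
  c("Lab results", "Got my labs back", "Confused about my results",
    "Advice please", "New results, thoughts?", "Venting", "Question")
}

#' Render one or two forum posts for a person in a given style
#'
#' Styles mirror the heterogeneous ways laboratory results appear in forum
#' text: full names with units, abbreviations, unitless numbers, alternate
#' units, mistyped unit labels, panels split across two same-day posts,
#' verbatim reposts on different days, and distractor posts with no results.
#'
#' @param person A person from [sample_cohort()].
#' @param style One of `forum_styles()`.
#' @param spec A `panel_spec`.
#' @param seed Optional integer seed for standalone reproducibility.
#' @param when POSIXct base timestamp for the post date.
#' @return A list with `posts` (data frame: `id`, `author`, `created_utc`,
#'   `title`, `selftext`) and `truth` (list per post: `contains_results`,
#'   `mentions` data frame).
#' @export
render_post <- function(person, style, spec, seed = NULL,
                        when = as.POSIXct("2019-06-01", tz = "UTC")) {
  if (!style %in% forum_styles()) stop("unknown style: ", style, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  day <- 86400
  ts <- as.numeric(when) + sample.int(day, 1) - 1
  mk_post <- function(suffix, ts, body) {
    data.frame(id = paste0(person$account, "-", suffix),
               author = person$account, created_utc = floor(ts),
               title = post_titles()[sample.int(7, 1)],
               selftext = body, stringsAsFactors = FALSE)
  }
  if (style == "distractor") {
    posts <- mk_post("d", ts, distractor_text())
    truth <- list(list(contains_results = FALSE, mentions = empty_truth()))
    return(list(posts = posts, truth = truth))
  }
  panel <- person$panel
  intro <- c("Just got my labs back.", "Finally got tested.",
             "Sharing my numbers for context.", "Got results today.")
  head_txt <- intro[sample.int(length(intro), 1)]
  if (style == "split-pair") {
    ids <- names(panel)
    if (length(ids) < 2) style <- "abbreviation-with-unit" else {
      half <- sample(ids, ceiling(length(ids) / 2))
      r1 <- render_lines(panel[half], spec, "abbreviation-with-unit")
      r2 <- render_lines(panel[setdiff(ids, half)], spec, "abbreviation-with-unit")
      # same UTC calendar day, a few hours apart
      ts1 <- as.numeric(when) + sample.int(day %/% 2, 1)
      ts2 <- ts1 + sample.int(day %/% 4, 1)
      posts <- rbind(mk_post("s1", ts1, paste(head_txt, r1$text)),
                     mk_post("s2", ts2, paste("Forgot to add:", r2$text)))
      r1$truth$style <- "split-pair"
      r2$truth$style <- "split-pair"
      truth <- list(list(contains_results = TRUE, mentions = r1$truth),
                    list(contains_results = TRUE, mentions = r2$truth))
      return(list(posts = posts, truth = truth))
    }
  }
  if (style == "duplicate-repost") {
    r <- render_lines(panel, spec, "abbreviation-with-unit")
    body <- paste(head_txt, r$text)
    ts2 <- ts + day * sample(2:30, 1)
    posts <- rbind(mk_post("r1", ts, body), mk_post("r2", ts2, body))
    r$truth$style <- "duplicate-repost"
    truth <- list(list(contains_results = TRUE, mentions = r$truth),
                  list(contains_results = TRUE, mentions = r$truth))
    return(list(posts = posts, truth = truth))
  }
  r <- render_lines(panel, spec, style)
  posts <- mk_post("m", ts, paste(head_txt, r$text))
  truth <- list(list(contains_results = TRUE, mentions = r$truth))
  list(posts = posts, truth = truth)
}

empty_truth <- function() {
  data.frame(test = character(0), value = numeric(0), rendered = character(0),
             unit = character(0), style = character(0), tol = numeric(0),
             stringsAsFactors = FALSE)
}

render_lines <- function(panel, spec, style) {
  frags <- character(0)
  truth <- empty_truth()
  for (id in names(panel)) {
    e <- spec[[id]]
    # demographic fields render plainly regardless of the requested style
    st <- if (id %in% c("age", "bmi")) "no-unit" else style
    if (id == "bmi") st <- "abbreviation-with-unit"
    m <- render_mention(id, e, panel[[id]], st)
    frags <- c(frags, m$text)
    truth <- rbind(truth, m$truth)
  }
  list(text = paste(frags, collapse = " "), truth = truth)
}

#' Generate a seeded synthetic forum corpus with ground truth
#'
#' Emulates a patient-forum dump: posts that embed laboratory results in
#' heterogeneous phrasings mixed with distractor posts, serialized in the
#' same JSON Lines dialect used by public Reddit archives. Every post is
#' covered by a ground-truth record suitable for evaluating screening and
#' extraction end to end.
#'
#' @param spec A `panel_spec`.
#' @param style_mix Named numeric weights over `forum_styles()`.
#' @param n_posts Number of posts to emit (pair styles produce two posts per
#'   event and are counted as two).
#' @param seed Integer seed.
#' @return A list with `posts` (data frame in archive dialect), `truth`
#'   (named list keyed by post id), and `persons`.
#' @export
generate_corpus <- function(spec,
                            style_mix = default_style_mix(),
                            n_posts = 2000, seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"))
  if (any(style_mix < 0) || !any(style_mix > 0)) {
    stop("style mix weights must be nonnegative with at least one positive",
         call. = FALSE)
  }
  unknown <- setdiff(names(style_mix), forum_styles())
  if (length(unknown)) stop("unknown style: ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  set.seed(seed)
  window_start <- as.POSIXct("2016-05-03", tz = "UTC")
  window_days <- 5 * 365
  posts <- list()
  truths <- list()
  persons <- list()
  n_emitted <- 0
  i_person <- 0
  w <- style_mix / sum(style_mix)
  pair_styles <- c("split-pair", "duplicate-repost")
  while (n_emitted < n_posts) {
    style <- sample(names(w), 1, prob = w)
    if (n_posts - n_emitted == 1 && style %in% pair_styles) {
      if (all(names(w)[w > 0] %in% pair_styles)) style <- "abbreviation-with-unit"
      else next
    }
    i_person <- i_person + 1
    person <- sample_person(spec, i_person)
    persons[[i_person]] <- person
    when <- window_start + 86400 * (sample.int(window_days, 1) - 1)
    r <- render_post(person, style, spec, seed = NULL, when = when)
    for (k in seq_len(nrow(r$posts))) {
      n_emitted <- n_emitted + 1
      id <- sprintf("t3_%06d", n_emitted)
      row <- r$posts[k, ]
      row$id <- id
      posts[[n_emitted]] <- row
      truths[[id]] <- r$truth[[k]]
    }
  }
  posts <- if (length(posts)) do.call(rbind, posts) else
    data.frame(id = character(0), author = character(0),
               created_utc = numeric(0), title = character(0),
               selftext = character(0), stringsAsFactors = FALSE)
  rownames(posts) <- NULL
  list(posts = posts, truth = truths, persons = persons)
}

#' Default posting-style mix
#'
#' Free parameters of the generator (the source forum's true style mix is
#' unobserved): half distractors, with result posts dominated by named and
#' abbreviated phrasings and mistyped units kept rare.
#' @return Named numeric weights summing to 1.
#' @export
default_style_mix <- function() {
  c("distractor" = 0.50, "full-name-with-unit" = 0.12,
    "abbreviation-with-unit" = 0.12, "no-unit" = 0.10,
    "alternate-unit" = 0.06, "mistyped-unit" = 0.02,
    "split-pair" = 0.04, "duplicate-repost" = 0.04)
}

#' Write posts as JSON Lines (public Reddit archive dialect)
#'
#' One JSON object per line with keys `id`, `author`, `created_utc`,
#' `title`, `selftext`.
#' @param posts Post data frame.
#' @param path Output path.
#' @export
write_posts <- function(posts, path) {
  lines <- vapply(seq_len(nrow(posts)), function(i) {
    jsonlite::toJSON(as.list(posts[i, c("id", "author", "created_utc",
                                        "title", "selftext")]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write or read corpus ground truth as JSON keyed by post id
#' @param truth Named list keyed by post id.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(entry) {
    m <- if (length(entry$mentions)) {
      do.call(rbind, lapply(entry$mentions, function(r) {
        data.frame(test = r$test, value = as.numeric(r$value),
                   rendered = as.character(r$rendered),
                   unit = as.character(r$unit), style = r$style,
                   tol = as.numeric(r$tol), stringsAsFactors = FALSE)
      }))
    } else empty_truth()
    list(contains_results = isTRUE(entry$contains_results), mentions = m)
  })
}
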