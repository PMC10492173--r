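#' Find raw laboratory mentions in a post
#'
#' Scans title and body for catalog synonyms followed (optionally through a
#' short filler such as "was", ":", "came back at") by a number and an
#' optional unit token. Overlapping matches are resolved to the longest
#' synonym, so "free t4 1.1" is free thyroxine, not free testosterone.
#' A captured trailing word is only treated as a unit when the catalog
#' recognizes it; anything else leaves the unit absent.
#'
#' @param post One-row post data frame (`id`, `author`, `created_utc`,
#'   `title`, `selftext`).
#' @param catalog A `lab_catalog`.
#' @return Data frame of raw mentions: `post_id`, `account`, `date`, `test`,
#'   `value`, `unit` (`NA` when absent), `start`, `end`.
#' @export
find_mentions <- function(post, catalog) {
  text <- tolower(paste(post$title, post$selftext))
  text <- gsub("µ|μ", "u", text)
  known_units <- all_known_units(catalog)
  filler <- "(?:\\s*[:=-]\\s*|\\s+)(?:(?:was|is|of|at|level|levels|came\\s+back\\s+at|came\\s+in\\s+at)(?:\\s*[:=-]\\s*|\\s+))?"
  num <- "([0-9]+(?:\\.[0-9]+)?)"
  # unit is captured through a zero-width lookahead so a following word is
  # never consumed (it may be the name of the next test in the panel)
  unit <- "(?=\\s*([a-z%][a-z0-9/%^\\.]*))?"
  hits <- list()
  for (id in names(catalog)) {
    for (syn in catalog[[id]]$synonyms) {
      syn_rx <- gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", tolower(syn), perl = TRUE)
      syn_rx <- gsub("\\s+", "\\\\s+", syn_rx)
      rx <- paste0("(?<![a-z0-9])(", syn_rx, ")", filler, num, unit)
      m <- gregexpr(rx, text, perl = TRUE)[[1]]
      if (m[1] == -1) next
      cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
      for (k in seq_along(m)) {
        val <- as.numeric(substr(text, cs[k, 2], cs[k, 2] + cl[k, 2] - 1))
        u <- if (cl[k, 3] > 0) substr(text, cs[k, 3], cs[k, 3] + cl[k, 3] - 1) else NA_character_
        if (!is.na(u) && !(normalize_unit(u) %in% known_units)) u <- NA_character_
        hits[[length(hits) + 1]] <- data.frame(
          post_id = post$id, account = post$author,
          date = as.character(as.Date(as.POSIXct(post$created_utc,
                                                 origin = "1970-01-01", tz = "UTC"))),
          test = id, value = val, unit = u,
          start = cs[k, 1], end = cs[k, 2] + cl[k, 2] - 1,
          syn_len = cl[k, 1], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(empty_mentions())
  out <- do.call(rbind, hits)
  # resolve overlapping synonym spans to the longest match
  out <- out[order(out$start, -out$syn_len), ]
  keep <- rep(TRUE, nrow(out))
  last_end <- -1
  for (k in seq_len(nrow(out))) {
    if (out$start[k] <= last_end) keep[k] <- FALSE
    else last_end <- out$end[k]
  }
  out <- out[keep, setdiff(names(out), "syn_len")]
  rownames(out) <- NULL
  out
}

empty_mentions <- function() {
  data.frame(post_id = character(0), account = character(0), date = character(0),
             test = character(0), value = numeric(0), unit = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' Convert a laboratory value to its canonical unit
#'
#' @param test Test id.
#' @param value Numeric value as written.
#' @param unit Unit name (canonical or a listed alternate).
#' @param catalog A `lab_catalog`.
#' @return Value in the canonical unit.
#' @export
convert_unit <- function(test, value, unit, catalog = lab_catalog()) {
  f <- unit_factor(catalog, test, unit)
  if (is.na(f)) {
    stop("unsupported unit '", unit, "' for test '", test, "'", call. = FALSE)
  }
  value * f
}

plausible_range <- function(catalog, test, widen = 1) {
  r <- catalog[[test]]$plausible
  c(r[1] / widen, r[2] * widen)
}

# candidate interpretations of a bare number: canonical value under each
# accepted unit, keeping only those inside the condition-plausible range
plausible_interpretations <- function(test, value, catalog, widen = 1) {
  t <- catalog[[test]]
  units <- c(t$unit, names(t$alt_units))
  facs <- c(1, unname(t$alt_units))
  r <- plausible_range(catalog, test, widen)
  canon <- value * facs
  ok <- canon >= r[1] & canon <= r[2]
  d <- data.frame(unit = units, factor = facs, canonical = canon,
                  stringsAsFactors = FALSE)[ok, , drop = FALSE]
  # identity-factor aliases (mIU/mL vs U/L) are one interpretation, not two
  d[!duplicated(signif(d$canonical, 9)), , drop = FALSE]
}

#' Check a value/unit pair for mistranscription
#'
#' A stated unit is accepted when the converted value lies in the
#' condition-plausible range; reinterpreted when the stated unit is
#' implausible (or not accepted for the test) and exactly one accepted unit
#' places the value inside the range; rejected otherwise.
#'
#' @param test,value,unit,catalog As in [convert_unit()].
#' @param widen Plausibility widening factor used during reprocessing.
#' @return List with `verdict` (`"accept"`, `"reinterpret"`, `"reject"`) and
#'   `unit` (the unit to use when verdict is not reject).
#' @export
check_mistranscription <- function(test, value, unit, catalog = lab_catalog(),
                                   widen = 1) {
  if (!is.finite(value) || value <= 0) {
    return(list(verdict = "reject", unit = NA_character_))
  }
  f <- unit_factor(catalog, test, unit)
  r <- plausible_range(catalog, test, widen)
  if (!is.na(f)) {
    v <- value * f
    if (v >= r[1] && v <= r[2]) return(list(verdict = "accept", unit = unit))
  }
  cand <- plausible_interpretations(test, value, catalog, widen)
  if (!is.na(f)) {
    cand <- cand[abs(cand$factor - f) > 1e-12, , drop = FALSE]
  }
  if (nrow(cand) == 1) list(verdict = "reinterpret", unit = cand$unit[1])
  else list(verdict = "reject", unit = NA_character_)
}

#' Resolve a mention's unit and convert to canonical form
#'
#' With a stated unit the value passes through the mistranscription check
#' and is converted. Without one, the value is evaluated against the
#' condition-plausible range under the canonical unit and every accepted
#' alternate: a single plausible interpretation converts cleanly; multiple
#' interpretations whose canonical values disagree by more than
#' `ambiguity` (a proportion) resolve to the canonical-unit reading when
#' plausible (otherwise the interpretation closest to the centre of the
#' healthy range) and are flagged uncertain; no plausible interpretation is
#' a rejection.
#'
#' @param test Test id.
#' @param value Number as written.
#' @param unit Unit as written, or `NA`/`NULL` when absent.
#' @param catalog A `lab_catalog`.
#' @param ambiguity Relative disagreement between interpretations above
#'   which the result is flagged uncertain.
#' @param widen Plausibility widening factor (reprocessing).
#' @return List: `value` (canonical), `uncertain`, `rejected`, `reason`.
#' @export
infer_unit <- function(test, value, unit = NA, catalog = lab_catalog(),
                       ambiguity = 0.2, widen = 1) {
  rejected <- function(reason) list(value = NA_real_, uncertain = NA,
                                    rejected = TRUE, reason = reason)
  if (!is.finite(value) || value <= 0) return(rejected("nonphysiological"))
  t <- catalog[[test]]
  if (is.null(t)) return(rejected("unknown-test"))
  if (!is.na(unit) && !is.null(unit) && nzchar(unit)) {
    chk <- check_mistranscription(test, value, unit, catalog, widen)
    if (chk$verdict == "reject") return(rejected("implausible-with-unit"))
    v <- convert_unit(test, value, chk$unit, catalog)
    return(list(value = v, uncertain = FALSE, rejected = FALSE,
                reason = if (chk$verdict == "reinterpret") "unit-reinterpreted" else "ok"))
  }
  cand <- plausible_interpretations(test, value, catalog, widen)
  if (!nrow(cand)) return(rejected("implausible-all-units"))
  if (nrow(cand) == 1) {
    return(list(value = cand$canonical[1], uncertain = FALSE,
                rejected = FALSE, reason = "ok"))
  }
  spread <- max(cand$canonical) / min(cand$canonical) - 1
  canonical_ok <- any(cand$factor == 1)
  pick <- if (canonical_ok) which(cand$factor == 1) else {
    mid <- sqrt(prod(pmax(t$healthy, 1e-12)))
    which.min(abs(log(cand$canonical) - log(mid)))
  }
  list(value = cand$canonical[pick], uncertain = spread > ambiguity,
       rejected = FALSE,
       reason = if (spread > ambiguity) "ambiguous-unit" else "ok")
}

#' Extract canonical laboratory observations from posts
#'
#' Runs [find_mentions()] and [infer_unit()] over a set of (typically
#' screen-flagged) posts. Rejected values are returned separately, never
#' silently dropped.
#'
#' @param posts Post data frame.
#' @param catalog A `lab_catalog`.
#' @param ambiguity Passed to [infer_unit()].
#' @return List with `observations` (data frame: `post_id`, `account`,
#'   `date`, `test`, `value`, `uncertain`, `raw_value`, `raw_unit`) and
#'   `rejections` (same shape plus `reason`).
#' @export
extract_observations <- function(posts, catalog = lab_catalog(),
                                 ambiguity = 0.2) {
  obs <- list(); rej <- list()
  for (i in seq_len(nrow(posts))) {
    men <- find_mentions(posts[i, ], catalog)
    for (k in seq_len(nrow(men))) {
      r <- infer_unit(men$test[k], men$value[k], men$unit[k], catalog,
                      ambiguity = ambiguity)
      row <- data.frame(post_id = men$post_id[k], account = men$account[k],
                        date = men$date[k], test = men$test[k],
                        value = r$value, uncertain = isTRUE(r$uncertain),
                        raw_value = men$value[k], raw_unit = men$unit[k],
                        reason = r$reason, stringsAsFactors = FALSE)
      if (r$rejected) rej[[length(rej) + 1]] <- row
      else obs[[length(obs) + 1]] <- row
    }
  }
  empty <- data.frame(post_id = character(0), account = character(0),
                      date = character(0), test = character(0),
                      value = numeric(0), uncertain = logical(0),
                      raw_value = numeric(0), raw_unit = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  list(observations = if (length(obs)) do.call(rbind, obs) else empty,
       rejections = if (length(rej)) do.call(rbind, rej) else empty)
}

#' Assemble observations into per-account, per-day test sets
#'
#' A test set — the unit of analysis — is all observations for one account
#' on one calendar day. Same-day repeats of a test with equal values
#' collapse to one observation; identical (test, value) pairs reposted by
#' the same account on a later day are dropped as duplicates; partial
#' panels split across same-day posts merge. Same-day repeats with
#' conflicting values are kept and the set is flagged for reprocessing.
#'
#' @param observations Observation data frame from [extract_observations()].
#' @return List with `observations` (with a `set_id` column) and `sets`
#'   (one row per test set: `set_id`, `account`, `date`, `age`, `bmi`,
#'   `conflict`).
#' @export
assemble_test_sets <- function(observations) {
  obs <- observations
  if (!nrow(obs)) {
    return(list(observations = cbind(obs, set_id = character(0)),
                sets = data.frame(set_id = character(0), account = character(0),
                                  date = character(0), age = numeric(0),
                                  bmi = numeric(0), conflict = logical(0),
                                  stringsAsFactors = FALSE)))
  }
  obs <- obs[order(obs$account, obs$date, obs$test), , drop = FALSE]
  # same account+day+test+value -> one observation (merging + same-day dedup)
  key_same <- paste(obs$account, obs$date, obs$test, signif(obs$value, 9))
  obs <- obs[!duplicated(key_same), , drop = FALSE]
  # identical (test, value) by the same account on a later day -> drop later
  # (obs are date-ordered, so duplicated() keeps the earliest posting)
  key_cross <- paste(obs$account, obs$test, signif(obs$value, 9))
  obs <- obs[!duplicated(key_cross), , drop = FALSE]
  obs$set_id <- paste(obs$account, obs$date, sep = "@")
  conflict_key <- paste(obs$set_id, obs$test)
  conflicted <- unique(obs$set_id[duplicated(conflict_key)])
  sets <- unique(obs[, c("set_id", "account", "date")])
  pull_field <- function(sid, test_id) {
    v <- obs$value[obs$set_id == sid & obs$test == test_id]
    if (length(v)) v[1] else NA_real_
  }
  sets$age <- vapply(sets$set_id, pull_field, numeric(1), "age")
  sets$bmi <- vapply(sets$set_id, pull_field, numeric(1), "bmi")
  sets$conflict <- sets$set_id %in% conflicted
  rownames(obs) <- NULL; rownames(sets) <- NULL
  list(observations = obs, sets = sets)
}

#' Add derived indices to assembled test sets
#'
#' Adds the LH/FSH ratio when both hormones are present (FSH > 0) and
#' HOMA-IR = fasting insulin (mU/L) x fasting glucose (mg/dL) / 405 when
#' both are present. Indices already posted by the account are never
#' overwritten.
#'
#' @param assembled Result of [assemble_test_sets()].
#' @return The same structure with derived observations appended.
#' @export
compute_derived <- function(assembled) {
  obs <- assembled$observations
  add <- list()
  for (sid in assembled$sets$set_id) {
    in_set <- obs[obs$set_id == sid, , drop = FALSE]
    one <- function(id) {
      v <- in_set$value[in_set$test == id]
      if (length(v) == 1) v else NA_real_
    }
    mk <- function(test_id, value, parents) {
      data.frame(post_id = "derived", account = in_set$account[1],
                 date = in_set$date[1], test = test_id, value = value,
                 uncertain = any(in_set$uncertain[in_set$test %in% parents]),
                 raw_value = NA_real_, raw_unit = NA_character_,
                 reason = "derived", set_id = sid, stringsAsFactors = FALSE)
    }
    if (!"lh_fsh" %in% in_set$test) {
      lh <- one("lh"); fsh <- one("fsh")
      if (is.finite(lh) && is.finite(fsh)) {
        if (fsh > 0) add[[length(add) + 1]] <- mk("lh_fsh", lh / fsh, c("lh", "fsh"))
        else warning("FSH is zero; LH/FSH ratio omitted for set ", sid)
      }
    }
    if (!"homa_ir" %in% in_set$test) {
      fi <- one("fi"); fpg <- one("fpg")
      if (is.finite(fi) && is.finite(fpg)) {
        add[[length(add) + 1]] <- mk("homa_ir", fi * fpg / 405, c("fi", "fpg"))
      }
    }
  }
  if (length(add)) assembled$observations <- rbind(obs, do.call(rbind, add))
  assembled
}
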