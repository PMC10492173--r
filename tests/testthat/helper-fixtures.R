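# Shared fixtures and independent oracles for the test suite.

# t CDF by numerical integration of the density (independent of pt()).
pt_oracle <- function(q, df) {
  lconst <- lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi)
  dens <- function(x) exp(lconst - (df + 1) / 2 * log1p(x^2 / df))
  if (q <= 0) {
    stats::integrate(dens, -Inf, q, rel.tol = 1e-12, abs.tol = 1e-12)$value
  } else {
    1 - stats::integrate(dens, q, Inf, rel.tol = 1e-12, abs.tol = 1e-12)$value
  }
}

# TOST p values recomputed from scratch through the integration oracle.
tost_oracle <- function(meanA, sdA, nA, meanB, sdB, nB, d = 0.499) {
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  b <- d * sp
  se <- sp * sqrt(1 / nA + 1 / nB)
  df <- nA + nB - 2
  delta <- meanA - meanB
  p_lower <- 1 - pt_oracle((delta + b) / se, df)
  p_upper <- pt_oracle((delta - b) / se, df)
  list(p = max(p_lower, p_upper), p_lower = p_lower, p_upper = p_upper,
       b = b, se = se, df = df)
}

# Mean of a normal truncated to [lo, hi] in closed form.
trunc_normal_mean <- function(m, s, lo, hi) {
  a <- (lo - m) / s
  b <- (hi - m) / s
  m + s * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# A small deterministic corpus shared across screening tests.
mini_corpus <- function(n_posts = 200, seed = 101) {
  spec <- default_panel_spec()
  generate_corpus(spec, n_posts = n_posts, seed = seed)
}

corpus_labels <- function(corp) {
  vapply(corp$truth, `[[`, logical(1), "contains_results")[corp$posts$id]
}

# Flattened truth mentions with account attribution.
truth_mentions <- function(corp) {
  acct <- stats::setNames(corp$posts$author, corp$posts$id)
  rows <- lapply(names(corp$truth), function(id) {
    m <- corp$truth[[id]]$mentions
    if (nrow(m)) cbind(post_id = id, m, account = acct[[id]],
                       stringsAsFactors = FALSE) else NULL
  })
  do.call(rbind, rows)
}

# Observation rows built directly (bypassing text) for QC tests.
make_obs <- function(values, test = "fsh", account = "acct1",
                     date = "2020-01-01", uncertain = FALSE) {
  n <- length(values)
  if (n == 0) {
    return(data.frame(post_id = character(0), account = character(0),
                      date = character(0), test = character(0),
                      value = numeric(0), uncertain = logical(0),
                      raw_value = numeric(0), raw_unit = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  }
  data.frame(post_id = sprintf("p%03d", seq_len(n)), account = account,
             date = date, test = test, value = values,
             uncertain = rep_len(uncertain, n), raw_value = values,
             raw_unit = NA_character_, reason = "ok",
             stringsAsFactors = FALSE)
}
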