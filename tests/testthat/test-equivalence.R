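studies <- literature_studies()

test_that("aggregate means are sample-size-weighted study means", {
  agg <- aggregate_mean(studies, "dheas")
  expect_identical(agg$n, 1288L)
  expect_equal(round(agg$mean, 1), 265.5)

  one <- aggregate_mean(studies[studies$study == "sova", ], "amh")
  expect_identical(one$n, 319L)
  expect_equal(one$mean, 9.3)

  toy <- data.frame(study = c("x", "y"), test = "t", n = c(50, 50),
                    mean = c(10, 20), sd = c(1, 1))
  expect_equal(aggregate_mean(toy, "t")$mean, 15)

  expect_error(aggregate_mean(studies, "hba1c"), "no study")
})

test_that("pooled SD follows the df-weighted variance formula", {
  expect_equal(pooled_sd(c(10, 10), c(2, 2)), 2)
  expect_equal(pooled_sd(c(2, 2), c(0, 2)), sqrt(2))
  expect_error(pooled_sd(c(1, 10), c(1, 1)), "group size")

  set.seed(41)
  for (k in 1:20) {
    n <- sample(2:50, 3, replace = TRUE)
    s <- runif(3, 0.5, 8)
    ps <- pooled_sd(n, s)
    expect_gte(ps, min(s) - 1e-12)
    expect_lte(ps, max(s) + 1e-12)
  }
})

test_that("TOST reproduces the FSH aggregate comparison", {
  tt <- tost(5.8, 3.1, 214, 5.9, 6.4, 1883)
  expect_true(tt$equivalent)
  expect_lt(tt$p, 0.001)
  expect_equal(tt$b, 0.499 * pooled_sd(c(214, 1883), c(3.1, 6.4)))

  # identical groups with large n: maximal evidence of equivalence
  big <- tost(10, 2, 5000, 10, 2, 5000)
  expect_lt(big$p, 1e-100)

  expect_error(tost(1, 0, 10, 1, 0, 10), "zero")
})

test_that("TOST p is monotone in the boundary and the mean difference", {
  p_at <- function(d, delta) tost(10 + delta, 4, 50, 10, 4, 60,
                                  boundary_spec(d = d))$p
  ds <- c(0.2, 0.4, 0.6, 0.9)
  ps <- vapply(ds, p_at, numeric(1), delta = 1)
  expect_true(all(diff(ps) < 0))          # larger boundary, easier equivalence
  deltas <- c(0, 0.5, 1, 2, 4)
  ps2 <- vapply(deltas, function(dl) p_at(0.499, dl), numeric(1))
  expect_true(all(diff(ps2) > 0))         # larger |difference|, harder
})

test_that("directional tests assign the side and are antisymmetric", {
  d <- directional_test(396.5, 165.2, 381, 265.5, 293.7, 1288)
  expect_identical(d$direction, "B-lower")
  expect_lt(d$p, 0.001)

  none <- directional_test(10, 3, 40, 10, 3, 40)
  expect_identical(none$direction, "none")

  a <- directional_test(12, 3, 40, 10, 4, 60)
  b <- directional_test(10, 4, 60, 12, 3, 40)
  expect_identical(a$direction, "B-lower")
  expect_identical(b$direction, "B-higher")
  expect_equal(a$p, b$p)
})

test_that("every comparison yields exactly one verdict", {
  set.seed(42)
  seen <- character(0)
  for (k in 1:60) {
    nA <- sample(5:300, 1); nB <- sample(5:300, 1)
    cmp <- compare_groups(runif(1, 0, 20), runif(1, 0.5, 8), nA,
                          runif(1, 0, 20), runif(1, 0.5, 8), nB)
    expect_true(cmp$verdict %in% c("equivalent", "literature-lower",
                                   "literature-higher", "inconclusive"))
    seen <- union(seen, cmp$verdict)
  }
  # the inconclusive state is genuinely representable
  inc <- compare_groups(10, 5, 10, 10.5, 5, 10)
  expect_identical(inc$verdict, "inconclusive")
  expect_identical(inc$code, "-")
})

test_that("the comparison matrix covers aggregate and per-study cells", {
  cmp <- compare_matrix(subreddit_summary(), studies,
                        aggregate = literature_aggregate())
  expect_identical(nrow(cmp$aggregate), 14L)
  expect_identical(nrow(cmp$per_study), 79L)
  # a test reported by zero studies never acquires per-study rows
  expect_false("hba1c" %in% cmp$per_study$test)
  # computed aggregate columns ride along for transparency
  expect_true(all(c("agg_n_calc", "agg_mean_calc") %in% names(cmp$aggregate)))

  # canonical-unit disagreement is a hard error before any test runs
  bad <- studies
  bad$unit[bad$test == "fsh"] <- "nmol/L"
  expect_error(compare_matrix(subreddit_summary(), bad,
                              aggregate = literature_aggregate()),
               "canonical unit")
})
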