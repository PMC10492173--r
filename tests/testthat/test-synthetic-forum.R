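test_that("full prevalence forces complete panels", {
  spec <- default_panel_spec()
  for (id in names(spec)) spec[[id]]$prevalence <- 1
  ppl <- sample_cohort(spec, 10, seed = 1)
  for (p in ppl) {
    expect_setequal(names(p$panel), names(spec))
    expect_true(all(p$panel > 0))
    expect_gt(p$age, 0)
    expect_gt(p$bmi, 0)
  }
})

test_that("cohort sampling is deterministic and matches its distribution", {
  spec <- default_panel_spec()
  a <- sample_cohort(spec, 50, seed = 7)
  b <- sample_cohort(spec, 50, seed = 7)
  expect_identical(a, b)

  # total testosterone sample mean vs the closed-form truncated-normal mean
  for (id in names(spec)) spec[[id]]$prevalence <- 1
  ppl <- sample_cohort(spec, 1000, seed = 7)
  tt <- vapply(ppl, function(p) p$panel[["total_t"]], numeric(1))
  e <- spec[["total_t"]]
  mu <- trunc_normal_mean(e$location, e$scale, e$plausible[1], e$plausible[2])
  expect_lt(abs(mean(tt) - mu), 3 * sd(tt) / sqrt(length(tt)))
})

test_that("invalid panel specs are rejected", {
  spec <- default_panel_spec()
  spec[["fsh"]]$scale <- -1
  expect_error(sample_cohort(spec, 5, seed = 1), "scale")
  spec2 <- default_panel_spec()
  spec2[["fsh"]]$prevalence <- 1.5
  expect_error(sample_cohort(spec2, 5, seed = 1), "prevalence")
})

test_that("rendering styles behave as specified", {
  spec <- default_panel_spec()
  person <- list(account = "user_x", age = 27, bmi = 24,
                 panel = c(fsh = 5.5), n_days = 1L)
  r <- render_post(person, "full-name-with-unit", spec, seed = 3)
  body <- tolower(paste(r$posts$title, r$posts$selftext))
  expect_true(grepl("follicle stimulating hormone", body))
  expect_true(grepl("5\\.5", body))
  expect_true(grepl("u/l", body))
  expect_true(r$truth[[1]]$contains_results)

  d <- render_post(person, "distractor", spec, seed = 3)
  expect_false(d$truth[[1]]$contains_results)
  expect_identical(nrow(d$truth[[1]]$mentions), 0L)

  g <- list(account = "user_y", age = 27, bmi = 24,
            panel = c(fpg = 90), n_days = 1L)
  a <- render_post(g, "alternate-unit", spec, seed = 5)
  m <- a$truth[[1]]$mentions
  expect_true(nzchar(m$unit))
  expect_lt(abs(as.numeric(m$rendered) * 18.016 - 90), 2 * m$tol + 1e-9)

  expect_error(render_post(person, "sonnet-form", spec), "unknown style")
})

test_that("pair styles share accounts and dates as specified", {
  spec <- default_panel_spec()
  person <- list(account = "user_z", age = 27, bmi = 24,
                 panel = c(fsh = 5.5, lh = 12, amh = 9.1), n_days = 1L)
  sp <- render_post(person, "split-pair", spec, seed = 11)
  expect_identical(nrow(sp$posts), 2L)
  days <- as.Date(as.POSIXct(sp$posts$created_utc, origin = "1970-01-01",
                             tz = "UTC"))
  expect_identical(days[1], days[2])
  both <- rbind(sp$truth[[1]]$mentions, sp$truth[[2]]$mentions)
  expect_setequal(both$test, c("fsh", "lh", "amh"))

  dr <- render_post(person, "duplicate-repost", spec, seed = 11)
  expect_identical(nrow(dr$posts), 2L)
  d2 <- as.Date(as.POSIXct(dr$posts$created_utc, origin = "1970-01-01",
                           tz = "UTC"))
  expect_true(d2[2] > d2[1])
  expect_identical(dr$truth[[1]]$mentions$value, dr$truth[[2]]$mentions$value)
})

test_that("corpus generation honors the style mix and covers truth", {
  spec <- default_panel_spec()
  all_noise <- generate_corpus(spec, c(distractor = 1), n_posts = 50, seed = 2)
  expect_identical(nrow(all_noise$posts), 50L)
  expect_true(all(!vapply(all_noise$truth, `[[`, logical(1), "contains_results")))

  mix <- c(distractor = 0.5, "abbreviation-with-unit" = 0.5)
  corp <- generate_corpus(spec, mix, n_posts = 2000, seed = 3)
  frac <- mean(vapply(corp$truth, `[[`, logical(1), "contains_results"))
  expect_gte(frac, 0.45)   # binomial 99% band at n = 2000
  expect_lte(frac, 0.55)
  expect_setequal(names(corp$truth), corp$posts$id)
  expect_identical(anyDuplicated(corp$posts$id), 0L)

  empty <- generate_corpus(spec, n_posts = 0, seed = 1)
  expect_identical(nrow(empty$posts), 0L)
  expect_length(empty$truth, 0)

  expect_error(generate_corpus(spec, c(distractor = -1), 10, seed = 1),
               "nonnegative")
})

test_that("identical seeds give byte-identical corpora and JSONL round-trips", {
  spec <- default_panel_spec()
  a <- generate_corpus(spec, n_posts = 120, seed = 9)
  b <- generate_corpus(spec, n_posts = 120, seed = 9)
  expect_identical(a$posts, b$posts)
  expect_identical(a$truth, b$truth)

  path <- withr::local_tempfile(fileext = ".jsonl")
  write_posts(a$posts, path)
  back <- load_posts(path)
  attr(back, "n_malformed") <- NULL
  expect_equal(back, a$posts)

  tpath <- withr::local_tempfile(fileext = ".json")
  write_truth(a$truth, tpath)
  tback <- read_truth(tpath)
  expect_equal(tback, a$truth, tolerance = 1e-12)
})

test_that("rendered values are faithful unit conversions of the truth", {
  catalog <- lab_catalog()
  corp <- mini_corpus(n_posts = 300, seed = 17)
  tm <- truth_mentions(corp)
  lab <- tm[tm$style != "mistyped-unit" & nzchar(tm$unit), , drop = FALSE]
  expect_gt(nrow(lab), 50)
  for (k in seq_len(nrow(lab))) {
    v <- convert_unit(lab$test[k], as.numeric(lab$rendered[k]), lab$unit[k],
                      catalog)
    expect_lt(abs(v - lab$value[k]), lab$tol[k] + 1e-9)
  }
  # label consistency: contains_results iff at least one rendered mention
  for (id in names(corp$truth)) {
    expect_identical(corp$truth[[id]]$contains_results,
                     nrow(corp$truth[[id]]$mentions) > 0)
  }
})
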