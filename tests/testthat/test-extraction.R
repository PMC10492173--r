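catalog <- lab_catalog()

mk_post <- function(text, id = "p1", author = "acct1", ts = 1577836800) {
  data.frame(id = id, author = author, created_utc = ts, title = "",
             selftext = text, stringsAsFactors = FALSE)
}

test_that("mentions are found with longest-synonym resolution", {
  m <- find_mentions(mk_post("FSH 5.5, LH 12"), catalog)
  expect_identical(m$test, c("fsh", "lh"))
  expect_equal(m$value, c(5.5, 12))
  expect_true(all(is.na(m$unit)))

  expect_identical(nrow(find_mentions(mk_post("so tired of this"), catalog)), 0L)

  # "free t4" must resolve to free thyroxine, not free testosterone
  m2 <- find_mentions(mk_post("my free t4 was 1.1 ng/dl"), catalog)
  expect_identical(m2$test, "ft4")

  # "hdl cholesterol" must not be eaten by the total-cholesterol synonym
  m3 <- find_mentions(mk_post("My HDL cholesterol was 56 mg/dl."), catalog)
  expect_identical(m3$test, "hdl")

  # the ratio wins over its component hormones, and a following mention of
  # the same hormone is still picked up
  m4 <- find_mentions(mk_post("lh/fsh: 2.3 fsh 10.9 U/L"), catalog)
  expect_identical(m4$test, c("lh_fsh", "fsh"))
  expect_identical(m4$unit[2], "u/l")
})

test_that("unit conversion applies catalog factors", {
  expect_lt(abs(convert_unit("dheas", 8.9, "umol/L", catalog) - 328), 0.5)
  expect_identical(convert_unit("fsh", 5.5, "U/L", catalog), 5.5)
  # glucose molar mass 180.16 g/mol -> 5.0 mmol/L is 90.1 mg/dL
  expect_lt(abs(convert_unit("fpg", 5.0, "mmol/L", catalog) - 90.08), 0.05)
  expect_error(convert_unit("fsh", 5.5, "parsec", catalog), "unsupported")

  # round trip to every alternate unit and back within 1 part in 1e6
  for (id in names(catalog)) {
    for (u in names(catalog[[id]]$alt_units)) {
      v <- mean(catalog[[id]]$healthy)
      f <- catalog[[id]]$alt_units[[u]]
      expect_lt(abs(convert_unit(id, v / f, u, catalog) - v) / v, 1e-6)
    }
  }
})

test_that("mistranscription verdicts follow the plausibility rules", {
  # high-but-condition-typical androgen is accepted as written
  expect_identical(check_mistranscription("total_t", 90, "ng/dL", catalog)$verdict,
                   "accept")
  # a DHEA-S of 8 ug/dL only makes sense in umol/L
  chk <- check_mistranscription("dheas", 8, "ug/dL", catalog)
  expect_identical(chk$verdict, "reinterpret")
  expect_identical(forumlabs:::normalize_unit(chk$unit), "umol/l")
  # nonphysiological values are rejected outright
  expect_identical(check_mistranscription("fsh", -3, "U/L", catalog)$verdict,
                   "reject")
})

test_that("unit inference resolves, flags, or rejects bare numbers", {
  r <- infer_unit("total_t", 90, NA, catalog)
  expect_equal(r$value, 90)
  expect_false(r$uncertain)
  expect_false(r$rejected)

  # progesterone at 15 is plausible both as ng/mL and as nmol/L
  r2 <- infer_unit("p", 15, NA, catalog)
  expect_false(r2$rejected)
  expect_true(r2$uncertain)
  expect_equal(r2$value, 15)  # canonical reading preferred

  r3 <- infer_unit("fsh", 5.5, "U/L", catalog)
  expect_equal(r3$value, 5.5)
  expect_false(r3$uncertain)

  # rejections are explicit records, not silent drops
  r4 <- infer_unit("fsh", 4000, NA, catalog)
  expect_true(r4$rejected)
  ext <- extract_observations(mk_post("my fsh was 4000"), catalog)
  expect_identical(nrow(ext$observations), 0L)
  expect_identical(nrow(ext$rejections), 1L)
  expect_identical(ext$rejections$reason, "implausible-all-units")

  # widened plausibility (the reprocessing pass) can rescue borderline values
  r5 <- infer_unit("fsh", 30, NA, catalog)
  expect_true(r5$rejected)
  r6 <- infer_unit("fsh", 30, NA, catalog, widen = 1.5)
  expect_false(r6$rejected)
})

test_that("test sets group, merge, and deduplicate per the analysis unit", {
  two <- rbind(make_obs(5.5, "fsh", "a1", "2020-01-01"),
               make_obs(12, "lh", "a1", "2020-01-01"))
  asm <- assemble_test_sets(two)
  expect_identical(nrow(asm$sets), 1L)
  expect_setequal(asm$observations$test, c("fsh", "lh"))

  # identical result reposted on a later day is dropped
  dup <- rbind(make_obs(5.5, "fsh", "a1", "2020-01-01"),
               make_obs(5.5, "fsh", "a1", "2020-03-01"))
  asm2 <- assemble_test_sets(dup)
  expect_identical(nrow(asm2$observations), 1L)
  expect_identical(asm2$observations$date, "2020-01-01")

  # conflicting same-day duplicates are kept and flagged
  con <- rbind(make_obs(5.5, "fsh", "a1", "2020-01-01"),
               make_obs(7.1, "fsh", "a1", "2020-01-01"))
  asm3 <- assemble_test_sets(con)
  expect_identical(nrow(asm3$observations), 2L)
  expect_true(asm3$sets$conflict)

  empty <- assemble_test_sets(make_obs(numeric(0)))
  expect_identical(nrow(empty$sets), 0L)

  # idempotence
  again <- assemble_test_sets(asm$observations[, setdiff(names(asm$observations), "set_id")])
  expect_equal(again$observations$value, asm$observations$value)
  expect_equal(again$sets$set_id, asm$sets$set_id)
})

test_that("derived indices are computed and never overwrite posted ones", {
  base <- rbind(make_obs(12, "lh"), make_obs(6, "fsh"))
  asm <- compute_derived(assemble_test_sets(base))
  ratio <- asm$observations[asm$observations$test == "lh_fsh", ]
  expect_equal(ratio$value, 2)

  homa <- rbind(make_obs(12, "fi"), make_obs(90, "fpg"))
  asm2 <- compute_derived(assemble_test_sets(homa))
  expect_equal(asm2$observations$value[asm2$observations$test == "homa_ir"],
               12 * 90 / 405)

  lone <- compute_derived(assemble_test_sets(make_obs(12, "fi")))
  expect_false("homa_ir" %in% lone$observations$test)

  posted <- rbind(make_obs(12, "fi"), make_obs(90, "fpg"),
                  make_obs(9.9, "homa_ir"))
  asm3 <- compute_derived(assemble_test_sets(posted))
  expect_equal(asm3$observations$value[asm3$observations$test == "homa_ir"], 9.9)
})

test_that("no surviving observation sits outside plausibility unless flagged", {
  corp <- mini_corpus(n_posts = 250, seed = 23)
  ext <- extract_observations(corp$posts, catalog)
  obs <- ext$observations
  for (k in seq_len(nrow(obs))) {
    r <- catalog[[obs$test[k]]]$plausible
    expect_true(obs$uncertain[k] ||
                  (obs$value[k] >= r[1] - 1e-9 & obs$value[k] <= r[2] + 1e-9))
  }
})
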