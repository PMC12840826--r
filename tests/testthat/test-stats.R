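# frequency statistic, dN/dS count ratio, presence, latitude trend

test_that("frequency statistic matches e = 100*g/(f+g) with half-away display", {
  expect_identical(snp_frequency(11, 110), 90.91)
  expect_identical(snp_frequency(0, 64), 100)
  expect_identical(snp_frequency(37, 0), 0)
  expect_identical(snp_frequency(105, 8), 7.08)    # 8/113
  expect_identical(snp_frequency(6, 102), 94.44)   # 102/108
  expect_error(snp_frequency(0, 0), class = "kdr_undefined_frequency")
  expect_error(snp_frequency(-1, 5), class = "kdr_input_error")

  # ties round away from zero, not to even: 1/800 = 0.125%
  expect_identical(snp_frequency(799, 1), 0.13)
  expect_identical(round_half_away(-0.125, 2), -0.13)

  # scale invariance of the underlying proportion
  for (k in c(2, 3, 10)) {
    expect_equal(snp_frequency(17 * k, 5 * k, digits = NULL),
                 snp_frequency(17, 5, digits = NULL))
  }
})

test_that("dN/dS count ratio and regime flags", {
  d <- dnds_count_ratio(6, 31)
  expect_equal(round_half_away(d$ratio, 2), 0.19)
  expect_identical(d$regime, "purifying-consistent")
  expect_match(d$caveat, "caution")
  expect_identical(dnds_count_ratio(3, 3)$ratio, 1)
  expect_identical(dnds_count_ratio(3, 3)$regime, "neutral-consistent")
  expect_identical(dnds_count_ratio(9, 3)$regime, "positive-consistent")
  expect_error(dnds_count_ratio(5, 0), class = "kdr_undefined_ratio")
})

test_that("presence is 'counts reported'; zero-change cells are flagged", {
  counts <- tibble::tibble(
    label      = c("A1B", "A1B", "A1B", "C2D", "E3F", "E3F"),
    population = c("P1",  "P2",  "P3",  "P2",  "P1",  "P2"),
    f = c(10L, 5L, 8L, 7L, 9L, 4L),
    g = c(2L,  1L, 0L, 3L, 1L, 2L)
  )
  ps <- presence_summary(counts, populations = c("P1", "P2", "P3"))
  expect_identical(ps$shared_in_all, 1L)   # A1B only
  expect_identical(ps$unique_to_one, 1L)   # C2D only
  expect_identical(ps$zero_change_cells$label, "A1B")
  pv <- ps$per_variant
  expect_identical(pv$max_population[pv$label == "E3F"], "P2")

  # single-population panel: everything reported is both shared and unique
  one <- presence_summary(counts[counts$population == "P1", ],
                          populations = "P1")
  expect_identical(one$shared_in_all, one$unique_to_one)
  expect_identical(one$shared_in_all, 2L)
})

test_that("frequency_table pivots long counts into a variant x population matrix", {
  counts <- tibble::tibble(label = c("X", "X", "Y"),
                           population = c("P1", "P2", "P2"),
                           f = c(1L, 0L, 3L), g = c(1L, 4L, 1L))
  m <- frequency_table(counts, populations = c("P1", "P2"))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m["X", "P1"], 50)
  expect_identical(m["Y", "P2"], 25)
  expect_true(is.na(m["Y", "P1"]))
})

test_that("latitude trend is a Spearman rank correlation with guards", {
  pops <- data.frame(name = c("MY", "TS", "DA", "TY", "JY"),
                     latitude = c(18.94, 18.79, 18.47, 18.31, 18.29))
  # perfectly monotone southward increase
  m922t <- c(MY = 58.46, TS = 62.07, DA = 72.09, TY = 80.58, JY = 90.91)
  expect_equal(latitude_trend(pops, m922t)$rho, -1)

  # non-monotone case checked against the explicit mid-rank oracle
  v1845i <- c(MY = 36.54, TS = 86.27, DA = 80.00, TY = 79.55, JY = 96.52)
  tr <- latitude_trend(pops, v1845i)
  expect_equal(tr$rho, oracle_spearman(pops$latitude, unname(v1845i)))
  expect_equal(tr$rho, -0.6)

  # antisymmetric under latitude negation
  neg <- pops; neg$latitude <- -neg$latitude
  expect_equal(latitude_trend(neg, v1845i)$rho, -tr$rho)

  # missing populations excluded pairwise
  part <- c(MY = 10, TS = NA, DA = 30, TY = 20, JY = 40)
  expect_identical(latitude_trend(pops, part)$n, 4L)

  # degenerate and insufficient inputs are flagged, not guessed
  expect_identical(latitude_trend(pops, c(MY = 5, TS = 5, DA = 5, TY = 5,
                                          JY = 5))$flag, "degenerate")
  expect_identical(latitude_trend(pops, c(MY = 1, TS = 2))$flag,
                   "insufficient-data")
})

test_that("summarize_variants bundles consistent full-dataset statistics", {
  fx <- vgsc_fixture()
  eff <- annotate_variants(fx$model, fx$variants)
  s <- summarize_variants(eff, fx$counts, populations = fx$populations)
  expect_identical(s$n_ns, 6L)
  expect_identical(s$n_s, 31L)
  expect_equal(s$dnds$ratio, 6 / 31)
  expect_identical(dim(s$frequency), c(37L, 5L))
  expect_identical(sum(s$presence), 128L)
  expect_identical(s$extremes$max$frequency[1], 100)
  # statistics computed on full precision, display on 2 dp
  expect_identical(s$frequency["N931N", "JY"], 7.08)
  expect_equal(s$frequency_full["N931N", "JY"], 100 * 8 / 113)
})
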