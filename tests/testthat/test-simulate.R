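# synthetic gene and observation generator

test_that("simulated genes are reproducible and valid", {
  cfg <- simulation_config(seed = 11, n_exons = 5, cds_length = 900,
                           genomic_length = 3000)
  g1 <- simulate_gene(cfg)
  g2 <- simulate_gene(cfg)
  expect_identical(g1, g2)                      # byte-identical given the seed
  expect_s3_class(validate_gene_model(g1), "gene_model")

  cds <- assemble_cds(g1)
  prot <- suppressWarnings(translate_cds(cds))
  expect_identical(substr(as.character(prot), 1, 1), "M")
  expect_identical(substr(as.character(prot), nchar(prot), nchar(prot)), "*")
  expect_length(attr(prot, "internal_stops"), 0)

  # a different seed gives a different gene
  expect_false(identical(g1$sequence,
                         simulate_gene(simulation_config(seed = 12,
                                                         n_exons = 5,
                                                         cds_length = 900,
                                                         genomic_length = 3000))$sequence))
})

test_that("the default configuration realises the target gene dimensions", {
  cfg <- simulation_config(seed = 3)
  gm <- simulate_gene(cfg)
  L <- gene_lengths(gm)
  expect_identical(L$genomic, 36774L)
  expect_identical(L$cds, 6414L)
  expect_identical(L$intron, 30360L)
  expect_identical(L$protein_positions, 2138L)
  expect_error(simulation_config(seed = 1, n_exons = 10, cds_length = 60),
               class = "kdr_config_error")
})

test_that("planted classes are recovered exactly by the annotation pipeline", {
  for (seed in c(2, 9)) {
    cfg <- simulation_config(seed = seed, n_exons = 4, cds_length = 3000,
                             genomic_length = 8000, n_variants = 40,
                             fraction_nonsynonymous = 0.25)
    gm <- simulate_gene(cfg)
    sim <- simulate_observations(gm, cfg)
    eff <- annotate_variants(gm, sim$variants)
    expect_identical(eff$effect_class,
                     sim$truth$true_class[match(eff$label, sim$truth$label)])
    parts <- partition_effects(eff)
    expect_identical(nrow(parts$nonsynonymous),
                     sum(sim$truth$true_class == "nonsynonymous"))
    expect_identical(nrow(parts$other), 0L)     # stops are never planted
  }
})

test_that("degenerate true frequency 1 gives f = 0 everywhere", {
  cfg <- simulation_config(seed = 5, n_exons = 3, cds_length = 1500,
                           genomic_length = 4000, n_variants = 10,
                           baseline_range = c(40, 40),  # logistic saturates at 1
                           missing_rate = 0)
  sim <- simulate_observations(simulate_gene(cfg), cfg)
  expect_true(all(sim$counts$f == 0L))
  expect_identical(nrow(sim$counts), 50L)       # no missing cells
})

test_that("estimated frequencies track truth within binomial error", {
  # depth fixed at 100; mean absolute error per cell should sit well under
  # 2*sqrt(p(1-p)/100) on average (the spec-level binomial standard error)
  errs <- c(); bound <- c()
  for (seed in 1:20) {
    cfg <- simulation_config(seed = seed, n_exons = 3, cds_length = 1800,
                             genomic_length = 5000, n_variants = 50,
                             depth_range = c(100, 100), missing_rate = 0)
    sim <- simulate_observations(simulate_gene(cfg), cfg)
    truth_p <- as.matrix(sim$truth[, paste0("p_", cfg$populations$name)])
    dimnames(truth_p) <- list(sim$truth$label, cfg$populations$name)
    est <- frequency_table(sim$counts, cfg$populations$name, digits = NULL) / 100
    est <- est[rownames(truth_p), colnames(truth_p)]
    errs <- c(errs, mean(abs(est - truth_p)))
    bound <- c(bound, mean(2 * sqrt(truth_p * (1 - truth_p) / 100)))
  }
  expect_lt(mean(errs), mean(bound))
})

test_that("Wilson 95% intervals cover the true frequency at the nominal rate", {
  cfg <- simulation_config(seed = 101, n_exons = 3, cds_length = 1500,
                           genomic_length = 4000, n_variants = 40,
                           depth_range = c(100, 100), missing_rate = 0,
                           baseline_range = c(-2, 2), trend_slope = 2)
  covered <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg$seed <- 100L + seed
    sim <- simulate_observations(simulate_gene(cfg), cfg)
    truth_p <- as.matrix(sim$truth[, paste0("p_", cfg$populations$name)])
    dimnames(truth_p) <- list(sim$truth$label, cfg$populations$name)
    for (i in seq_len(nrow(sim$counts))) {
      n <- sim$counts$f[i] + sim$counts$g[i]
      ci <- suppressWarnings(prop.test(sim$counts$g[i], n,
                                       correct = FALSE))$conf.int
      p <- truth_p[sim$counts$label[i], sim$counts$population[i]]
      covered <- covered + (p >= ci[1] && p <= ci[2])
      total <- total + 1L
    }
  }
  expect_gte(total, 1000L)
  expect_gt(covered / total, 0.92)
  expect_lt(covered / total, 0.98)
})

test_that("the generator leaves the global RNG stream untouched", {
  set.seed(99); before <- .Random.seed
  invisible(simulate_gene(simulation_config(seed = 7, n_exons = 3,
                                            cds_length = 300,
                                            genomic_length = 600)))
  expect_identical(.Random.seed, before)
})
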