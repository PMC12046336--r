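test_that("fixed seed fixes every emitted byte", {
  cfg <- simulation_config(n_patients = 80, n_snps = 30, seed = 101)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  export_cohort(c1, d1); export_cohort(c2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ## different seed changes output
  c3 <- simulate_cohort(simulation_config(n_patients = 80, n_snps = 30,
                                          seed = 102))
  expect_false(identical(c1$dosage, c3$dosage))
})

test_that("degenerate configs error; invariants hold on the snp table", {
  expect_error(simulation_config(n_snps = 0), "n_snps")
  expect_error(simulation_config(driver_freqs = c(0, 0.5),
                                 n_drivers = 2), "driver_freqs")
  co <- fixture_cohort()
  recomputed <- apply(co$dosage, 2, dqtltools:::.maf_from_dosage)
  expect_equal(unname(recomputed), co$snp_table$maf, tolerance = 1e-12)
  expect_false(any(duplicated(rownames(co$dosage))))
  expect_true(all(co$snp_table$maf >= 0.01))
})

test_that("ld_decay = 0 with 2 ancestral haplotypes gives D' = 1 in-block", {
  cfg <- simulation_config(n_patients = 300, n_snps = 20,
                           n_ancestral_haplotypes = 2L, ld_decay = 0,
                           seed = 5)
  g <- simulate_genotypes(cfg)
  b1 <- g$snp_table$id[g$snp_table$block_id == g$snp_table$block_id[1]]
  for (j in seq_along(b1)[-1]) {
    ld <- two_locus_ld(g$dosage[, b1[1]], g$dosage[, b1[j]])
    expect_equal(ld$d_prime, 1, tolerance = 1e-9)
  }
})

test_that("SNPs in different blocks are uncorrelated (r2 ~ 0)", {
  cfg <- simulation_config(n_patients = 900, n_snps = 40, ld_decay = 0.5,
                           seed = 6)
  g <- simulate_genotypes(cfg)
  st <- g$snp_table
  blocks <- unique(st$block_id)
  r2 <- c()
  for (i in seq_len(min(4, length(blocks) - 1))) {
    a <- st$id[st$block_id == blocks[i]][1]
    b <- st$id[st$block_id == blocks[i + 1]][1]
    r2 <- c(r2, two_locus_ld(g$dosage[, a], g$dosage[, b])$r2)
  }
  expect_true(all(sqrt(r2) < 3 / sqrt(900)))
})

test_that("driver frequencies hit their targets (no planted effects)", {
  cfg <- simulation_config(n_patients = 10000, n_snps = 12,
                           n_drivers = 3, driver_freqs = c(0.2, 0.2, 0.2),
                           seed = 9)
  co <- simulate_cohort(cfg)
  f <- colMeans(co$drivers)
  ## binomial SE at n = 10,000 is ~0.004; 3 SE band
  expect_true(all(abs(f - 0.2) < 0.012))
})

test_that("planted log-odds are recovered from the genotype table", {
  pe <- data.frame(snp_id = "snp0001", driver_id = "driver01",
                   per_allele_log_odds = log(2))
  cfg <- simulation_config(n_patients = 20000, n_snps = 12, n_drivers = 2,
                           driver_freqs = c(0.3, 0.2),
                           planted_effects = pe, ld_decay = 0.3, seed = 10)
  co <- simulate_cohort(cfg)
  ## crude 2 x 3 odds-ratio estimate per allele: logistic fit on dosage only
  d <- co$dosage[, "snp0001"]; y <- co$drivers[, "driver01"]
  or_hat <- exp(coef(glm(y ~ d, family = binomial()))[2])
  expect_equal(unname(or_hat), 2, tolerance = 0.15)
  ## null driver independent of genotype
  chi <- suppressWarnings(
    chisq.test(table(co$dosage[, "snp0002"], co$drivers[, "driver02"])))
  expect_gt(chi$p.value, 0.001)
})

test_that("unreachable target frequency errors, naming the driver", {
  ## every patient's linear predictor saturates high: a low marginal
  ## frequency cannot be reached by any intercept in the search range
  expect_error(dqtltools:::.solve_intercept(rep(30, 100), 0.3,
                                            driver_id = "driver01"),
               "driver01")
  ## unknown ids caught
  pe2 <- data.frame(snp_id = "nope", driver_id = "driver01",
                    per_allele_log_odds = 1)
  cfg2 <- simulation_config(n_patients = 50, n_snps = 12, n_drivers = 1,
                            driver_freqs = 0.5, planted_effects = pe2,
                            seed = 3)
  expect_error(simulate_cohort(cfg2), "nope")
})

test_that("loop anchor simulation honors the cell-line support rule", {
  cfg <- simulation_config(n_patients = 50, n_snps = 40, seed = 12)
  co <- simulate_cohort(cfg)
  drv <- co$driver_meta[1, ]
  drv_rs <- region_set(drv$chrom, drv$start, drv$end,
                       strategy = "linear", driver_id = drv$id)
  far_snp <- co$snp_table$id[which.max(abs(co$snp_table$pos -
                                           (drv$start + drv$end) / 2))]
  mk <- function(ncl) simulate_loop_anchors(
    cfg, co$snp_table, co$driver_meta,
    planted_loops = data.frame(driver_id = drv$id, snp_id = far_snp,
                               n_cell_lines = ncl, target = "RNAPII"),
    n_background = 0L)
  ## one cell line: excluded by the >= 2 rule
  sp1 <- spatial_regions(drv_rs, mk(1), min_cell_lines = 2,
                         exclude = linear_window(drv_rs, 5e5))
  expect_equal(nrow(sp1$intervals), 0L)
  ## two cell lines: the distal window appears
  sp2 <- spatial_regions(drv_rs, mk(2), min_cell_lines = 2,
                         exclude = linear_window(drv_rs, 5e5))
  expect_equal(nrow(sp2$intervals), 1L)
  expect_true(far_snp %in% snps_in_regions(co$snp_table, sp2))
  ## fraction = 0 plants nothing anywhere
  none <- simulate_loop_anchors(cfg, co$snp_table, co$driver_meta,
                                fraction = 0, n_background = 0L)
  expect_equal(nrow(none$pairs), 0L)
})

test_that("molecular traits: null p-values uniform, planted beta covered", {
  co <- fixture_cohort()
  tr0 <- simulate_molecular_traits(co, NULL, n_traits = 40, seed = 31)
  p0 <- vapply(1:40, function(i)
    summary(lm(tr0$tumor[i, ] ~ co$dosage[, 1]))$coefficients[2, 4],
    numeric(1))
  expect_gt(suppressWarnings(ks.test(p0, "punif")$p.value), 0.01)
  ## coverage of the planted beta over replicates (reduced n for runtime)
  cover <- vapply(1:120, function(r) {
    pq <- data.frame(snp_id = "snp0005", trait_id = "trait001",
                     beta = 0.5)
    tr <- simulate_molecular_traits(co, pq, n_traits = 2, seed = 1000 + r)
    fit <- summary(lm(tr$tumor[1, ] ~ co$dosage[, "snp0005"] +
                        co$covariates$age +
                        co$covariates$PC1))$coefficients[2, 1:2]
    abs(fit[1] - 0.5) < 1.96 * fit[2]
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1.0)
})

test_that("ancestry panels: Fst = 0 reproduces cohort frequencies", {
  co <- fixture_cohort()
  cfg <- simulation_config(n_patients = 50, n_snps = 12, seed = 2,
                           ancestry_panels = list(
                             populations = c(pop1 = 1000, pop2 = 500),
                             fst = c(0, 0.15)))
  af <- simulate_ancestry_freqs(co, cfg, snp_ids = co$snp_table$id[1:5])
  base <- vapply(co$snp_table$id[1:5], function(s)
    dqtltools:::.aaf_from_dosage(co$dosage[, s]), numeric(1))
  expect_equal(af$vaf[af$population == "pop1"], unname(base))
  expect_false(all(af$vaf[af$population == "pop2"] == unname(base)))
})
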