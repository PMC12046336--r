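test_that("maf_filter is strict and matches brute force", {
  d <- cbind(a = rep(c(0L, 1L), c(180, 20)),      # maf 0.05
             b = rep(c(0L, 1L), c(100, 100)),     # maf 0.25
             c = rep(0:2, c(50, 100, 50)))        # maf 0.5
  co <- list(dosage = d)
  expect_identical(maf_filter(co, 0.05), c("b", "c"))
  expect_identical(maf_filter(co, 0), c("a", "b", "c"))
  set.seed(2)
  d2 <- sapply(runif(30, 0.01, 0.5), function(f) rbinom(300, 2, f))
  colnames(d2) <- sprintf("s%02d", 1:30)
  brute <- colnames(d2)[apply(d2, 2, function(x) {
    f <- sum(x) / (2 * length(x)); min(f, 1 - f) > 0.1
  })]
  expect_identical(maf_filter(list(dosage = d2), 0.1), brute)
})

test_that("coefficients match a from-scratch Newton-Raphson oracle", {
  set.seed(3)
  n <- 400
  cv <- toy_covariates(n)
  d <- rbinom(n, 2, 0.3)
  eta <- -1 + 0.6 * d + 0.3 * cv$PC1
  y <- rbinom(n, 1, plogis(eta))
  res <- fit_driver_model(d, y, cv, driver_type = "cna_loss")
  X <- cbind(1, d, cv$PC1, cv$PC2, cv$PC3, cv$PC4, cv$PC5, cv$age, cv$pga)
  o <- oracle_logistic(X, y)
  expect_equal(res$beta, unname(o$beta[2]), tolerance = 1e-6)
  expect_equal(res$se, unname(o$se[2]), tolerance = 1e-6)
  expect_false(res$separation_flag)
  expect_equal(res$or_, exp(res$beta), tolerance = 1e-12)
})

test_that("degenerate inputs: constant dosage, single-class driver, separation", {
  n <- 120
  cv <- toy_covariates(n)
  y <- rbinom(n, 1, 0.4)
  r <- fit_driver_model(rep(1, n), y, cv)
  expect_true(r$separation_flag)
  expect_true(is.na(r$beta))
  expect_error(fit_driver_model(rbinom(n, 2, 0.3), rep(1, n), cv),
               "single class")
  ## perfectly separated genotype: flagged, Firth gives finite estimate
  d <- rep(c(0, 2), each = n / 2)
  ysep <- rep(c(0, 1), each = n / 2)
  rsep <- fit_driver_model(d, ysep, cv)
  expect_true(rsep$separation_flag)
  expect_true(is.finite(rsep$beta))
})

test_that("missing genotypes are excluded complete-case", {
  set.seed(8)
  n <- 300
  cv <- toy_covariates(n)
  d <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, 0.3)
  d_miss <- d; d_miss[1:25] <- NA
  r <- fit_driver_model(d_miss, y, cv)
  r2 <- fit_driver_model(d[-(1:25)], y[-(1:25)],
                         cv[-(1:25), , drop = FALSE])
  expect_equal(r$n_used, 275L)
  expect_equal(r$beta, r2$beta, tolerance = 1e-12)
})

test_that("scan_risk: BH over the grid, missing SNPs skipped", {
  co <- fixture_cohort()
  expect_warning(r <- scan_risk(co, c("snp0001", "snp0002", "absent"),
                                drivers = colnames(co$drivers)[1:3]),
                 "absent")
  expect_equal(nrow(r), 6L)
  expect_equal(r$q, p.adjust(r$p, "BH"))
  ## BH arithmetic on a known vector
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH"),
               c(0.003, 0.03, 0.9))
  ## empty grid warns and returns empty
  expect_warning(expect_warning(
    e <- scan_risk(co, "absent", drivers = colnames(co$drivers)[1])))
  expect_equal(nrow(e), 0L)
})

test_that("scan_local: threshold arithmetic and zero-SNP region", {
  co <- fixture_cohort()
  rs <- region_set("chr1", 1, max(co$snp_table$pos), strategy = "linear",
                   driver_id = "driver09")
  sc <- scan_local(co, "driver09", "linear", rs, max_span_snps = 15)
  expect_equal(sc$threshold, 0.1 / sc$n_blocks)
  expect_equal(unique(sc$results$threshold), sc$threshold)
  expect_identical(sc$results$significant,
                   !is.na(sc$results$p) & sc$results$p < sc$threshold)
  ## 10 singleton blocks -> threshold 0.01
  ind <- sapply(1:10, function(i) rbinom(400, 2, 0.4))
  colnames(ind) <- sprintf("i%02d", 1:10)
  st <- data.frame(id = colnames(ind), chrom = "chr9", pos = 1:10 * 1e5,
                   ref = "A", alt = "G",
                   maf = apply(ind, 2, function(x) min(mean(x) / 2,
                                                       1 - mean(x) / 2)))
  co2 <- co
  co2$dosage <- cbind(co$dosage, ind)
  co2$snp_table <- rbind(co$snp_table[, names(st)], st)
  sc2 <- scan_local(co2, "driver09", "linear",
                    region_set("chr9", 1, 2e6, strategy = "linear"))
  expect_equal(sc2$n_blocks, 10L)
  expect_equal(sc2$threshold, 0.01)
  ## empty region
  sc3 <- scan_local(co, "driver09", "linear",
                    region_set("chrX", 1, 100, strategy = "linear"))
  expect_equal(nrow(sc3$results), 0L)
  expect_equal(sc3$n_blocks, 0L)
})

test_that("scan output is invariant to SNP input order", {
  co <- fixture_cohort()
  ids <- co$snp_table$id[1:12]
  r1 <- scan_risk(co, ids, drivers = "driver05")
  r2 <- scan_risk(co, rev(ids), drivers = "driver05")
  r2 <- r2[match(r1$snp_id, r2$snp_id), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("select_tag_snps picks the argmin with leftmost tie-break", {
  bs <- structure(list(blocks = list(c("a", "b", "c"), "d"),
                       strong_fraction = c(1, NA),
                       snp_ids = c("a", "b", "c", "d")),
                  class = "HaplotypeBlockSet")
  res <- data.frame(snp_id = c("a", "b", "c", "d"),
                    driver_id = "x", strategy = "linear",
                    p = c(0.002, 0.0005, 0.01, 0.5),
                    pos = c(100, 200, 300, 400),
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  tg <- select_tag_snps(res, bs)
  expect_identical(tg$snp_id, "b")
  ## tie in p: leftmost position wins
  res$p <- c(0.001, 0.001, 0.01, 0.5)
  expect_identical(select_tag_snps(res, bs)$snp_id, "a")
  ## random fixture equals argmin oracle
  set.seed(12)
  res$p <- runif(4); res$significant <- rep(TRUE, 4)
  tg2 <- select_tag_snps(res, bs)
  expect_identical(tg2$snp_id[1],
                   res$snp_id[which.min(res$p[1:3])])
})

test_that("index event adjustment: no confounding leaves beta unchanged", {
  set.seed(13)
  co <- fixture_cohort()
  base <- fit_driver_model(co$dosage[, 3], co$drivers[, 4],
                           co$covariates, "cna_loss",
                           snp_id = co$snp_table$id[3],
                           driver_id = "driver04", strategy = "linear")
  adj <- index_event_adjustment(base, co)
  ## clinical covariates were simulated independent of genotype
  expect_equal(adj$beta, base$beta, tolerance = 0.12)
  expect_match(adj$strategy, "clinical")
  ## degenerate T category dropped with warning
  co2 <- co
  co2$covariates$T_category <- "T2"
  expect_warning(index_event_adjustment(base, co2), "degenerate")
})

test_that("Wald CIs cover planted effects at the nominal rate", {
  ## property check at reduced scale; acceptance covers the full version
  set.seed(14)
  n <- 1200
  cover <- vapply(1:150, function(r) {
    d <- rbinom(n, 2, 0.3)
    cv <- toy_covariates(n, seed = r)
    y <- rbinom(n, 1, plogis(-1.2 + log(2) * d))
    res <- fit_driver_model(d, y, cv)
    abs(res$beta - log(2)) < 1.959964 * res$se
  }, logical(1))
  expect_gt(mean(cover), 0.90)
})
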