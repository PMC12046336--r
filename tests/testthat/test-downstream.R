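test_that("tumor specificity is exactly the 8-case truth table", {
  mk <- function(q, b) data.frame(snp_id = "s", trait_id = "t", beta = b,
                                  q = q, stringsAsFactors = FALSE)
  cases <- expand.grid(q_t = c(0.05, 0.5), q_r = c(0.05, 0.5),
                       same_sign = c(TRUE, FALSE))
  expected <- with(cases, q_t < 0.1 & (q_r > 0.1 | !same_sign))
  for (i in seq_len(nrow(cases))) {
    tt <- tumor_specificity(mk(cases$q_t[i], 1),
                            mk(cases$q_r[i],
                               if (cases$same_sign[i]) 1 else -1))
    expect_identical(tt$tumor_specific, expected[i], info = paste(i))
  }
  ## unmatched pair -> NA
  un <- tumor_specificity(mk(0.05, 1),
                          data.frame(snp_id = "s", trait_id = "other",
                                     beta = 1, q = 0.5))
  expect_true(is.na(un$tumor_specific))
})

test_that("rank inverse normal is invariant to monotone transforms", {
  set.seed(31)
  x <- rlnorm(100)
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(log(x)))
  expect_equal(rank_inverse_normal(x), rank_inverse_normal(rank(x)))
  expect_equal(mean(rank_inverse_normal(x)), 0, tolerance = 1e-10)
})

test_that("molecular_qtl: planted QTL detected, permuted genotypes null", {
  co <- fixture_cohort()
  pq <- data.frame(snp_id = "snp0004", trait_id = "trait005", beta = 0.6)
  tr <- simulate_molecular_traits(co, pq, n_traits = 25, seed = 41)
  r <- molecular_qtl("snp0004", co, tr$tumor, tr$trait_meta,
                     n_factors = 5)
  hit <- r[r$trait_id == "trait005", ]
  expect_true(hit$significant)
  expect_equal(r$q, p.adjust(r$p, "BH"))
  expect_true(all(r$q >= r$p - 1e-12))
  ## permuting genotypes kills the association (uniform p)
  co_perm <- co
  set.seed(42)
  co_perm$dosage <- co$dosage[sample(nrow(co$dosage)), ]
  rownames(co_perm$dosage) <- rownames(co$dosage)
  rp <- molecular_qtl("snp0004", co_perm, tr$tumor, tr$trait_meta,
                      n_factors = 5)
  expect_gt(min(rp$q), 0.05)
  ## rank-inverse-normal route invariant to monotone trait transforms
  tr_exp <- tr$tumor; tr_exp[] <- exp(tr_exp)
  r1 <- molecular_qtl("snp0004", co, tr$tumor, tr$trait_meta,
                      transform = "rin", n_factors = 0)
  r2 <- molecular_qtl("snp0004", co, tr_exp, tr$trait_meta,
                      transform = "rin", n_factors = 0)
  expect_equal(r1$p, r2$p, tolerance = 1e-10)
  ## zero traits in window
  far <- tr$trait_meta; far$pos <- far$pos + 1e9
  expect_equal(nrow(molecular_qtl("snp0004", co, tr$tumor, far)), 0L)
})

test_that("Fisher test equals exact table enumeration (margins <= 40)", {
  set.seed(51)
  tables <- list(c(8, 2, 1, 5), c(3, 17, 12, 8), c(1, 1, 1, 1),
                 c(20, 0, 5, 15), c(2, 38, 9, 31))
  for (tb in tables) {
    p_pkg <- fisher.test(matrix(tb, 2, 2))$p.value
    p_orc <- oracle_fisher_two_sided(tb[1], tb[3], tb[2], tb[4])
    expect_equal(p_pkg, unname(p_orc), tolerance = 1e-9)
  }
})

test_that("vaf_ancestry_test reconstructs counts and flags zero margins", {
  ft <- data.frame(
    snp = rep(c("rs_a", "rs_b"), each = 2),
    population = rep(c("european", "african"), 2),
    vaf = c(0.10, 0.066, 0.2, 0.2),
    n_individuals = c(7718, 4359, 1000, 500))
  r <- vaf_ancestry_test(ft)
  expect_lt(r$fisher_p[r$snp == "rs_a"], 0.01)
  ## equal VAF, same direction: p near 1, OR near 1
  rb <- r[r$snp == "rs_b", ]
  expect_gt(rb$fisher_p, 0.5)
  expect_equal(rb$allele_or, 1, tolerance = 0.1)
  ## zero margin
  ft0 <- data.frame(snp = "z", population = c("european", "african"),
                    vaf = c(0, 0), n_individuals = c(100, 100))
  r0 <- vaf_ancestry_test(ft0)
  expect_equal(r0$fisher_p, 1)
  expect_false(r0$or_defined)
  ## q computed within population comparison
  expect_equal(r$q[r$population == "african"],
               p.adjust(r$fisher_p[r$population == "african"], "BH"))
})

test_that("explained fraction: zero cases, variants recorded, guard", {
  expect_equal(explained_fraction(5, 1, 0.3, 0.1)$fraction, 0)
  expect_equal(explained_fraction(5, 2.5, 0.2, 0.2)$fraction, 0)
  r <- explained_fraction(5, 2.5, 0.10, 0.066, variant = "all")
  expect_identical(r$formula_variant,
                   c("delta2", "delta1", "attributable"))
  expect_true(all(is.finite(r$fraction)))
  expect_equal(r$fraction[1], 2 * r$fraction[2], tolerance = 1e-12)
  expect_error(explained_fraction(1, 2, 0.3, 0.1), "undefined")
})

test_that("skew test: determinism, frequency preservation, extremes", {
  set.seed(61)
  n <- 150
  cv <- toy_covariates(n)
  dos <- sapply(1:6, function(i) rbinom(n, 2, 0.3))
  y <- rbinom(n, 1, 0.3)
  calls <- 0L
  scan_cb <- function(lab) {
    calls <<- calls + 1L
    expect_equal(sum(lab), sum(y))   # frequency preserved exactly
    vapply(1:6, function(i)
      fit_driver_model(dos[, i], lab, cv)$p, numeric(1))
  }
  s1 <- pvalue_skew_test(scan_cb, y, n_perm = 25, seed = 5)
  s2 <- pvalue_skew_test(scan_cb, y, n_perm = 25, seed = 5)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$null_skew, s2$null_skew)
  ## strong planted signal: observed skew beats every permutation
  y_strong <- rbinom(n, 1, plogis(-2 + 3 * dos[, 1]))
  scan_strong <- function(lab) vapply(1:6, function(i)
    fit_driver_model(dos[, i], lab, cv)$p, numeric(1))
  s3 <- pvalue_skew_test(scan_strong, y_strong, n_perm = 50, seed = 6,
                         add_one = TRUE)
  expect_equal(s3$p, 1 / 51, tolerance = 0.06)
  ## too few p-values
  expect_error(pvalue_skew_test(function(l) c(0.1, 0.2), y, n_perm = 2),
               "3 p-values")
})

test_that("qtl enrichment permutation: determinism and planted extreme", {
  pool <- sprintf("s%03d", 1:60)
  tags <- pool[1:5]
  ## pipeline: replicated QTLs exist only at tag SNPs
  pipe <- function(snps) {
    hits <- snps %in% tags
    list(n_snps_involved = sum(hits), n_qtls = 3L * sum(hits))
  }
  r <- qtl_enrichment_permutation(tags, pool, pipe, n_iter = 100,
                                  seed = 3)
  r2 <- qtl_enrichment_permutation(tags, pool, pipe, n_iter = 100,
                                   seed = 3)
  expect_identical(r, r2)
  expect_equal(r$p_snps_involved, 0)   # study estimator can hit 0
  ra <- qtl_enrichment_permutation(tags, pool, pipe, n_iter = 100,
                                   seed = 3, add_one = TRUE)
  expect_equal(ra$p_snps_involved, 1 / 101)
  expect_error(qtl_enrichment_permutation(pool, pool[1:3], pipe),
               "smaller")
})

test_that("pi0 estimates: uniform, strong signal, mixtures, fallback", {
  set.seed(71)
  expect_gt(pi0_estimate(runif(10000)), 0.93)
  expect_lt(pi0_estimate(runif(5000, 0, 0.009)), 0.05)
  mix <- c(runif(7000), rbeta(3000, 0.08, 8))
  expect_equal(pi0_estimate(mix), 0.7, tolerance = 0.06)
  expect_warning(p <- pi0_estimate(runif(10)), "fewer than 20")
  expect_true(p >= 0 && p <= 1)
})

test_that("clinical association picks the generative coding at large n", {
  set.seed(81)
  n <- 2500
  cv <- toy_covariates(n)
  d <- rbinom(n, 2, 0.4)
  ## dominant-generative phenotype
  y_dom <- 2 * (d >= 1) + rnorm(n)
  r_dom <- clinical_association(d, y_dom, "linear", cv)
  expect_identical(r_dom$best, "dominant")
  ## additive phenotype: codominant captures it but costs a df; the
  ## winning model must carry an overwhelmingly significant LRT
  y_add <- 0.8 * d + rnorm(n)
  r_add <- clinical_association(d, y_add, "linear", cv)
  expect_lt(r_add$fits$p[r_add$fits$coding == r_add$best], 1e-10)
  ## null phenotype: genotype p uniform-ish, no tiny p
  r_null <- clinical_association(d, rnorm(n), "linear", cv)
  expect_gt(min(r_null$fits$p), 1e-4)
  ## recessive skipped without homozygotes
  d2 <- pmin(d, 1)
  r2 <- clinical_association(d2, y_dom, "linear", cv)
  expect_identical(r2$skipped, "recessive")
  expect_false("recessive" %in% r2$fits$coding)
  ## ordinal and logistic kinds run
  r3 <- clinical_association(d, sample(1:5, n, TRUE), "ordinal", cv)
  expect_true(r3$best %in% c("dominant", "recessive", "codominant"))
  r4 <- clinical_association(d, rbinom(n, 1, 0.4), "logistic", cv)
  expect_true(all(is.finite(r4$fits$aic)))
})
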