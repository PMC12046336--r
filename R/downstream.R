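## Characterization of dQTLs: molecular QTL models, tumor specificity,
## permutation enrichment, ancestry VAF bias and explained fraction,
## p-value-distribution diagnostics, and clinical genetic-model selection.

## top-k principal components of the covariate-residualized trait matrix;
## stand-in for latent-factor (PEER-style) noise adjustment
.latent_factors <- function(traits, covariates, k = 10L) {
  k <- min(k, nrow(traits) - 1L, ncol(traits) - 1L)
  if (k < 1L) return(NULL)
  Xc <- cbind(1, covariates$PC1, covariates$PC2, covariates$PC3,
              covariates$PC4, covariates$PC5, covariates$age)
  R <- t(traits) - Xc %*% qr.coef(qr(Xc), t(traits))   # patients x traits
  pc <- svd(scale(R, scale = FALSE), nu = k, nv = 0L)
  pc$u[, seq_len(k), drop = FALSE]
}

#' Molecular QTL scan around a SNP
#'
#' Tests every trait within `window` bp of the SNP with a linear model
#' trait ~ dosage + PC1-5 + age + latent factors, where the latent factors
#' are the top principal components of the covariate-residualized trait
#' matrix (a variance-capture stand-in for external factor inference).
#' Expression traits should be rank inverse-normal transformed
#' (`transform = "rin"`); methylation beta values are left on their
#' native scale. p-values are BH-adjusted within the scan.
#'
#' @param snp_id SNP to test.
#' @param cohort a `Cohort` (genotypes, covariates, snp_table).
#' @param traits traits x patients matrix.
#' @param trait_meta data.frame `trait_id`, `chrom`, `pos`.
#' @param window half-width in bp (default 500 kbp).
#' @param transform `"none"` (default) or `"rin"`.
#' @param n_factors latent factors to include (default 10).
#' @param q_threshold significance cutoff (default 0.1).
#' @param cohort_label label copied into results.
#' @return data.frame of `MolecularQTLResult`s: `snp_id`, `trait_id`,
#'   `beta`, `se`, `p`, `q`, `cohort`, `significant`; zero rows when no
#'   trait lies in the window.
#' @export
molecular_qtl <- function(snp_id, cohort, traits, trait_meta,
                          window = 5e5, transform = c("none", "rin"),
                          n_factors = 10L, q_threshold = 0.1,
                          cohort_label = "discovery") {
  transform <- match.arg(transform)
  si <- match(snp_id, cohort$snp_table$id)
  if (is.na(si)) stop("unknown SNP: ", snp_id, call. = FALSE)
  pos <- cohort$snp_table$pos[si]
  chrom <- cohort$snp_table$chrom[si]
  in_win <- trait_meta$chrom == chrom &
    abs(trait_meta$pos - pos) <= window
  ids <- trait_meta$trait_id[in_win]
  if (!length(ids))
    return(data.frame(snp_id = character(), trait_id = character(),
                      beta = numeric(), se = numeric(), p = numeric(),
                      q = numeric(), cohort = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  d <- cohort$dosage[, snp_id]
  cv <- cohort$covariates
  Y <- traits[ids, , drop = FALSE]
  if (transform == "rin") Y <- t(apply(Y, 1L, rank_inverse_normal))
  lf <- .latent_factors(traits, cv, n_factors)
  ok <- !is.na(d) & complete.cases(t(Y))
  X <- cbind(1, d, cv$PC1, cv$PC2, cv$PC3, cv$PC4, cv$PC5, cv$age,
             if (!is.null(lf)) lf)
  X <- X[ok, , drop = FALSE]
  Yk <- t(Y[, ok, drop = FALSE])           # patients x traits
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Yk)
  resid <- Yk - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtXinv[2L, 2L])
  beta <- coefs[2L, ]
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  out <- data.frame(snp_id = snp_id, trait_id = ids, beta = beta, se = se,
                    p = p, q = p.adjust(p, method = "BH"),
                    cohort = cohort_label, stringsAsFactors = FALSE)
  out$significant <- !is.na(out$q) & out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Tumor specificity of molecular QTLs
#'
#' A (SNP, trait) QTL is tumor-specific when Q_tumor < `q_cut` and either
#' Q_reference > `q_cut` or the tumor and reference effects have opposite
#' signs. Unmatched pairs get `NA`.
#'
#' @param tumor_results,reference_results [molecular_qtl()] outputs.
#' @param q_cut cutoff (default 0.10).
#' @return `tumor_results` with a `tumor_specific` column.
#' @export
tumor_specificity <- function(tumor_results, reference_results,
                              q_cut = 0.10) {
  key <- function(x) paste(x$snp_id, x$trait_id, sep = "\r")
  m <- match(key(tumor_results), key(reference_results))
  q_r <- reference_results$q[m]
  b_r <- reference_results$beta[m]
  out <- tumor_results
  out$tumor_specific <- ifelse(
    is.na(m), NA,
    tumor_results$q < q_cut &
      (q_r > q_cut | sign(tumor_results$beta) != sign(b_r)))
  out
}

#' Permutation enrichment of molecular QTLs at tag SNPs
#'
#' Draws `n_iter` random SNP sets of the tag-set size from the evaluated
#' pool, reruns the supplied QTL discovery(+replication) pipeline on each,
#' and compares two statistics with their null distributions: the number
#' of SNPs involved in at least one replicated QTL, and the total number
#' of replicated QTLs. The default estimator is the study convention
#' p = #\{null >= observed\} / n_iter; `add_one = TRUE` uses
#' (1 + #\{null >= observed\}) / (1 + n_iter), which cannot return 0.
#'
#' @param tag_snps character vector of tag SNP ids.
#' @param snp_pool pool of evaluated SNP ids (must contain enough SNPs).
#' @param qtl_pipeline function(snp_ids) returning a list/vector with
#'   `n_snps_involved` and `n_qtls`.
#' @param n_iter permutations (default 1000).
#' @param seed integer seed.
#' @param add_one use the permutation-inclusive estimator.
#' @return list with `p_snps_involved`, `p_total_qtls`, `observed`,
#'   `null_snps_involved`, `null_total_qtls`.
#' @export
qtl_enrichment_permutation <- function(tag_snps, snp_pool, qtl_pipeline,
                                       n_iter = 1000L, seed = 1L,
                                       add_one = FALSE) {
  if (length(snp_pool) < length(tag_snps))
    stop("snp_pool smaller than tag set", call. = FALSE)
  obs <- qtl_pipeline(tag_snps)
  set.seed(seed)
  null_snps <- integer(n_iter); null_qtls <- integer(n_iter)
  for (i in seq_len(n_iter)) {
    draw <- sample(snp_pool, length(tag_snps))
    r <- qtl_pipeline(draw)
    null_snps[i] <- r[["n_snps_involved"]]
    null_qtls[i] <- r[["n_qtls"]]
  }
  est <- function(null, o) if (add_one)
    (1 + sum(null >= o)) / (1 + n_iter) else sum(null >= o) / n_iter
  list(p_snps_involved = est(null_snps, obs[["n_snps_involved"]]),
       p_total_qtls = est(null_qtls, obs[["n_qtls"]]),
       observed = obs, null_snps_involved = null_snps,
       null_total_qtls = null_qtls)
}

#' Ancestry allele-frequency (VAF) bias tests
#'
#' Reconstructs allele counts from published population VAFs (alt count =
#' round(vaf x 2n)) and runs a two-sided Fisher exact test of each
#' comparison population against the reference population, per SNP. FDR is
#' applied across SNPs within each population comparison separately. The
#' reported odds ratio is the conditional maximum-likelihood estimate.
#'
#' @param freq_table data.frame `snp`, `population`, `vaf`,
#'   `n_individuals`.
#' @param reference reference population label (default `"european"`).
#' @return data.frame `AncestryVAFRecord`s: `snp`, `population`,
#'   `vaf_ref`, `vaf_pop`, `n_ref`, `n_pop`, `allele_or`, `fisher_p`, `q`,
#'   `or_defined`.
#' @export
vaf_ancestry_test <- function(freq_table, reference = "european") {
  stopifnot(all(c("snp", "population", "vaf", "n_individuals") %in%
                names(freq_table)))
  ref <- freq_table[freq_table$population == reference, , drop = FALSE]
  if (!nrow(ref)) stop("reference population absent", call. = FALSE)
  cmp <- freq_table[freq_table$population != reference, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cmp)), function(i) {
    r <- ref[match(cmp$snp[i], ref$snp), , drop = FALSE]
    if (!nrow(r) || is.na(r$snp))
      stop("SNP missing in reference population: ", cmp$snp[i],
           call. = FALSE)
    a1 <- round(cmp$vaf[i] * 2 * cmp$n_individuals[i])
    a0 <- 2 * cmp$n_individuals[i] - a1
    b1 <- round(r$vaf * 2 * r$n_individuals)
    b0 <- 2 * r$n_individuals - b1
    tab <- matrix(c(a1, a0, b1, b0), 2L, 2L)
    zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (zero_margin) {
      p <- 1; orr <- NA_real_
    } else {
      ft <- fisher.test(tab)
      p <- ft$p.value; orr <- unname(ft$estimate)
    }
    data.frame(snp = cmp$snp[i], population = cmp$population[i],
               vaf_ref = r$vaf, vaf_pop = cmp$vaf[i],
               n_ref = r$n_individuals, n_pop = cmp$n_individuals[i],
               allele_or = orr, fisher_p = p, or_defined = !zero_margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  for (pop in unique(out$population)) {
    idx <- out$population == pop
    out$q[idx] <- p.adjust(out$fisher_p[idx], method = "BH")
  }
  out
}

#' Fraction of an ancestral somatic difference explained by a dQTL
#'
#' The published construction compares an ancestry-somatic odds ratio with
#' the dQTL odds ratio scaled by the normalized VAF difference between the
#' two populations. The sentence underdetermines the formula, so a small
#' family of variants is exposed and the variant used is always recorded:
#' \describe{
#'   \item{`"delta2"` (default)}{2 (vaf1 - vaf2) log(OR_dqtl) /
#'     log(OR_ancestry) — per-genome allele-dosage difference.}
#'   \item{`"delta1"`}{(vaf1 - vaf2) log(OR_dqtl) / log(OR_ancestry) —
#'     per-allele difference.}
#'   \item{`"attributable"`}{(OR_dqtl^(2 (vaf1 - vaf2)) - 1) /
#'     (OR_ancestry - 1) — odds-scale attributable share.}
#' }
#'
#' @param or_ancestry ancestry-somatic odds ratio (> 0, not 1).
#' @param or_dqtl dQTL odds ratio (> 0).
#' @param vaf_pop1,vaf_pop2 population allele frequencies.
#' @param variant formula variant (see above), or `"all"` for every
#'   variant.
#' @return data.frame `ExplainedFraction`: `fraction`, `formula_variant`,
#'   inputs echoed.
#' @export
explained_fraction <- function(or_ancestry, or_dqtl, vaf_pop1, vaf_pop2,
                               variant = c("delta2", "delta1",
                                           "attributable", "all")) {
  variant <- match.arg(variant)
  stopifnot(or_ancestry > 0, or_dqtl > 0)
  if (or_ancestry == 1)
    stop("explained fraction undefined for or_ancestry = 1", call. = FALSE)
  dv <- vaf_pop1 - vaf_pop2
  f <- c(delta2 = 2 * dv * log(or_dqtl) / log(or_ancestry),
         delta1 = dv * log(or_dqtl) / log(or_ancestry),
         attributable = (or_dqtl^(2 * dv) - 1) / (or_ancestry - 1))
  use <- if (variant == "all") names(f) else variant
  data.frame(fraction = unname(f[use]), formula_variant = use,
             or_ancestry = or_ancestry, or_dqtl = or_dqtl,
             delta_vaf = dv, stringsAsFactors = FALSE)
}

## moment skewness; requires >= 3 values
.skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop("skewness undefined for < 3 values", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

#' Permutation test for skew of a dQTL p-value distribution
#'
#' Reruns a full per-driver scan with permuted driver labels (a
#' permutation of the binary vector, which preserves the driver frequency
#' exactly in every iteration) and compares the skewness of the observed
#' -log10 p distribution with the permutation null. The study estimator is
#' p = #\{perm skew > observed\} / n_perm; `add_one = TRUE` uses the
#' inclusive variant.
#'
#' @param scan_callable function(driver_labels) returning the scan's
#'   p-value vector.
#' @param driver_labels observed binary driver vector.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param add_one permutation-inclusive estimator.
#' @return list with `p`, `observed_skew`, `null_skew`.
#' @export
pvalue_skew_test <- function(scan_callable, driver_labels, n_perm = 1000L,
                             seed = 1L, add_one = FALSE) {
  pv <- scan_callable(driver_labels)
  pv <- pv[!is.na(pv)]
  if (length(pv) < 3L)
    stop("scan yielded < 3 p-values; skew undefined", call. = FALSE)
  obs <- .skewness(-log10(pmax(pv, .Machine$double.xmin)))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(driver_labels)
    pvn <- scan_callable(perm)
    pvn <- pvn[!is.na(pvn)]
    .skewness(-log10(pmax(pvn, .Machine$double.xmin)))
  }, numeric(1))
  p <- if (add_one) (1 + sum(null > obs)) / (1 + n_perm)
       else sum(null > obs) / n_perm
  list(p = p, observed_skew = obs, null_skew = null)
}

#' Storey estimate of the proportion of true nulls
#'
#' pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) over a lambda grid,
#' extrapolated to lambda -> 1 with a cubic smoothing spline and clipped
#' to [0, 1]. With fewer than 20 p-values the estimator falls back to the
#' single point lambda = 0.5 with a warning.
#'
#' @param p_values vector in [0, 1].
#' @param lambda_grid grid (default 0.05 to 0.95 by 0.05).
#' @return pi0 estimate in [0, 1].
#' @export
pi0_estimate <- function(p_values, lambda_grid = seq(0.05, 0.95, 0.05)) {
  p_values <- p_values[!is.na(p_values)]
  .assert_prob(p_values, "p_values", open = FALSE)
  m <- length(p_values)
  if (m < 20L) {
    warning("fewer than 20 p-values; using fixed lambda = 0.5",
            call. = FALSE)
    return(min(1, max(0, mean(p_values > 0.5) / 0.5)))
  }
  pi0_l <- vapply(lambda_grid, function(l) mean(p_values > l) / (1 - l),
                  numeric(1))
  fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
  min(1, max(0, predict(fit, x = max(lambda_grid))$y))
}

#' Clinical association with genetic-model selection
#'
#' Codes the genotype three ways — dominant (any alt allele), recessive
#' (two alt alleles) and codominant (each genotype its own level) — fits
#' each coding with five genetic principal components (plus age where
#' requested), and reports the model with the lowest AIC. Phenotype kinds:
#' linear (PSA, age), logistic (binary T category), ordinal (ISUP grade
#' group, via proportional-odds regression). A recessive coding with no
#' homozygous-alt carriers is skipped with a note.
#'
#' @param dosage genotype dosages in \{0, 1, 2, NA\}.
#' @param phenotype response vector (factor or ordered for logistic /
#'   ordinal).
#' @param kind `"linear"`, `"logistic"` or `"ordinal"`.
#' @param covariates data.frame with `PC1`..`PC5` and `age`.
#' @param adjust_age include age as a covariate (default TRUE; set FALSE
#'   when the phenotype is age itself).
#' @return list with `best` (winning coding name), `fits` (data.frame of
#'   coding, AIC, p from a likelihood-ratio test against the no-genotype
#'   model), `skipped`.
#' @export
clinical_association <- function(dosage, phenotype,
                                 kind = c("linear", "logistic", "ordinal"),
                                 covariates, adjust_age = TRUE) {
  kind <- match.arg(kind)
  ok <- !is.na(dosage) & !is.na(phenotype)
  d <- dosage[ok]
  y <- phenotype[ok]
  cv <- covariates[ok, , drop = FALSE]
  base <- data.frame(PC1 = cv$PC1, PC2 = cv$PC2, PC3 = cv$PC3,
                     PC4 = cv$PC4, PC5 = cv$PC5)
  if (adjust_age) base$age <- cv$age
  codings <- list(dominant = as.numeric(d >= 1),
                  recessive = as.numeric(d == 2),
                  codominant = factor(d, levels = sort(unique(d))))
  skipped <- character()
  if (sum(d == 2) == 0L) {
    skipped <- "recessive"
    codings$recessive <- NULL
  }
  fit_one <- function(g) {
    df <- cbind(base, g = g, y = y)
    null_df <- cbind(base, y = y)
    if (kind == "linear") {
      f <- lm(y ~ ., data = df); f0 <- lm(y ~ ., data = null_df)
      pv <- stats::anova(f0, f)$`Pr(>F)`[2L]
    } else if (kind == "logistic") {
      yb <- if (is.factor(y)) as.integer(y) - 1L else as.numeric(y)
      df$y <- yb; null_df$y <- yb
      f <- stats::glm(y ~ ., data = df, family = binomial())
      f0 <- stats::glm(y ~ ., data = null_df, family = binomial())
      pv <- stats::anova(f0, f, test = "LRT")$`Pr(>Chi)`[2L]
    } else {
      yo <- if (is.ordered(y)) y else factor(y, ordered = TRUE)
      df$y <- yo; null_df$y <- yo
      f <- MASS::polr(y ~ ., data = df, Hess = TRUE)
      f0 <- MASS::polr(y ~ ., data = null_df, Hess = TRUE)
      lr <- 2 * (stats::logLik(f) - stats::logLik(f0))
      pv <- pchisq(as.numeric(lr),
                   df = attr(stats::logLik(f), "df") -
                        attr(stats::logLik(f0), "df"),
                   lower.tail = FALSE)
    }
    c(aic = AIC(f), p = pv)
  }
  res <- t(vapply(codings, fit_one, numeric(2)))
  fits <- data.frame(coding = rownames(res), aic = res[, "aic"],
                     p = res[, "p"], stringsAsFactors = FALSE)
  rownames(fits) <- NULL
  list(best = fits$coding[which.min(fits$aic)], fits = fits,
       skipped = skipped)
}
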