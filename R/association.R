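## The dQTL scan: per-SNP logistic regression with covariate adjustment,
## strategy-specific multiple testing, and tag-SNP selection.

## Maximum-likelihood logistic fit on a prebuilt design matrix, with
## complete-separation detection and a Firth-type penalized fallback.
## Returns the coefficient/SE for column `focus`.
.fit_logistic <- function(X, y, focus = 2L) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  eps <- 1e-8
  sep <- any(fit$fitted.values > 1 - eps | fit$fitted.values < eps) &&
    max(abs(fit$coefficients), na.rm = TRUE) > 10
  converged <- isTRUE(fit$converged)
  if (!sep && converged && !anyNA(fit$coefficients)) {
    w <- fit$weights
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (!is.null(cov)) {
      return(list(beta = fit$coefficients[focus],
                  se = sqrt(cov[focus, focus]),
                  converged = TRUE, separation = FALSE, method = "ml"))
    }
  }
  ## Firth penalized likelihood: score modified by hat-diagonal term
  firth <- .fit_firth(X, y, focus = focus)
  firth$separation <- TRUE
  firth
}

.fit_firth <- function(X, y, focus = 2L, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(w))
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) return(list(beta = NA_real_, se = NA_real_,
                                  converged = FALSE, separation = TRUE,
                                  method = "firth"))
    H <- rowSums((X %*% inv) * X) * w          # hat diagonal
    U <- drop(crossprod(X, y - mu + H * (0.5 - mu)))
    step <- drop(inv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  cov <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  list(beta = beta[focus],
       se = if (is.null(cov)) NA_real_ else sqrt(cov[focus, focus]),
       converged = converged, separation = TRUE, method = "firth")
}

## burden covariate matched to driver type: PGA for CNA/fusion, SNV density
## for SNV drivers
.burden_for <- function(covariates, driver_type) {
  if (identical(driver_type, "snv")) covariates$snv_density
  else covariates$pga
}

.base_design <- function(dosage, covariates, driver_type,
                         extra_covariates = NULL) {
  X <- cbind(1, dosage,
             covariates$PC1, covariates$PC2, covariates$PC3,
             covariates$PC4, covariates$PC5, covariates$age,
             .burden_for(covariates, driver_type))
  colnames(X) <- c("(Intercept)", "dosage", paste0("PC", 1:5), "age",
                   "burden")
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.matrix(extra_covariates)
    X <- cbind(X, extra_covariates)
  }
  X
}

#' Fit the per-SNP driver logistic model
#'
#' Logistic regression of a binary somatic driver on additive SNP dosage,
#' adjusting for the first five genetic principal components, age, and the
#' type-matched somatic mutation burden (PGA for CNA/fusion drivers, SNV
#' density for SNV drivers). Missing genotypes are handled by complete-case
#' exclusion. Complete separation triggers a flagged Firth-type penalized
#' fallback fit.
#'
#' @param dosage numeric dosage vector in \{0, 1, 2, NA\}.
#' @param driver binary vector (both classes must be present).
#' @param covariates data.frame with `PC1`..`PC5`, `age`, `pga`,
#'   `snv_density`.
#' @param driver_type one of `"cna_gain"`, `"cna_loss"`, `"snv"`,
#'   `"fusion"` (selects the burden covariate).
#' @param extra_covariates optional numeric matrix of additional columns.
#' @param snp_id,driver_id,strategy labels copied into the result.
#' @return one-row data.frame (an `AssociationResult`): `snp_id`,
#'   `driver_id`, `strategy`, `beta`, `se`, `or_`, `p`, `threshold`,
#'   `significant`, `q`, `n_used`, `converged`, `separation_flag`.
#' @export
fit_driver_model <- function(dosage, driver, covariates,
                             driver_type = "cna_loss",
                             extra_covariates = NULL,
                             snp_id = NA_character_,
                             driver_id = NA_character_,
                             strategy = NA_character_) {
  stopifnot(length(dosage) == length(driver))
  ok <- !is.na(dosage) & !is.na(driver)
  if (!is.null(extra_covariates))
    ok <- ok & complete.cases(as.matrix(extra_covariates))
  d <- dosage[ok]; y <- driver[ok]
  if (length(unique(y)) < 2L)
    stop("driver has a single class; association undefined", call. = FALSE)
  res <- data.frame(snp_id = snp_id, driver_id = driver_id,
                    strategy = strategy, beta = NA_real_, se = NA_real_,
                    or_ = NA_real_, p = NA_real_, threshold = NA_real_,
                    significant = NA, q = NA_real_, n_used = length(y),
                    converged = FALSE, separation_flag = FALSE,
                    stringsAsFactors = FALSE)
  if (length(unique(d)) < 2L) {            # degenerate genotype column
    res$separation_flag <- TRUE
    return(res)
  }
  X <- .base_design(d, covariates[ok, , drop = FALSE], driver_type,
                    if (is.null(extra_covariates)) NULL
                    else as.matrix(extra_covariates)[ok, , drop = FALSE])
  fit <- .fit_logistic(X, y)
  res$beta <- fit$beta
  res$se <- fit$se
  res$or_ <- exp(fit$beta)
  res$p <- if (is.na(fit$beta) || is.na(fit$se) || fit$se == 0) NA_real_
           else 2 * pnorm(-abs(fit$beta / fit$se))
  res$converged <- fit$converged
  res$separation_flag <- fit$separation
  res
}

#' MAF filter
#'
#' SNPs whose cohort minor allele frequency (recomputed from the dosage
#' matrix, complete-case) is strictly greater than `min_maf`.
#'
#' @param cohort a `Cohort` (or list with `dosage`).
#' @param min_maf threshold in [0, 0.5]; boundary values are excluded.
#' @param snp_ids optional subset to filter (default all SNPs).
#' @return character vector of retained SNP ids.
#' @export
maf_filter <- function(cohort, min_maf = 0.05, snp_ids = NULL) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  snp_ids <- snp_ids %||% colnames(cohort$dosage)
  maf <- vapply(snp_ids, function(s) .maf_from_dosage(cohort$dosage[, s]),
                numeric(1))
  snp_ids[!is.na(maf) & maf > min_maf]
}

#' Drivers eligible for the dQTL scan
#'
#' Drivers with cohort frequency at least `min_freq` (default 5%).
#'
#' @param cohort a `Cohort`.
#' @param min_freq minimum frequency (default 0.05).
#' @return character vector of driver ids.
#' @export
eligible_drivers <- function(cohort, min_freq = 0.05) {
  f <- colMeans(cohort$drivers, na.rm = TRUE)
  names(f)[f >= min_freq]
}

## scan a SNP id set against one driver; shared by all strategies
.scan_snps <- function(cohort, snp_ids, driver_id, strategy) {
  meta <- cohort$driver_meta
  dtype <- meta$type[match(driver_id, meta$id)]
  y <- cohort$drivers[, driver_id]
  rows <- lapply(snp_ids, function(s)
    fit_driver_model(cohort$dosage[, s], y, cohort$covariates,
                     driver_type = dtype, snp_id = s,
                     driver_id = driver_id, strategy = strategy))
  out <- do.call(rbind, rows)
  if (is.null(out)) return(.empty_results())
  out$pos <- cohort$snp_table$pos[match(out$snp_id, cohort$snp_table$id)]
  out
}

.empty_results <- function() {
  data.frame(snp_id = character(), driver_id = character(),
             strategy = character(), beta = numeric(), se = numeric(),
             or_ = numeric(), p = numeric(), threshold = numeric(),
             significant = logical(), q = numeric(), n_used = integer(),
             converged = logical(), separation_flag = logical(),
             pos = integer(), stringsAsFactors = FALSE)
}

#' Risk-SNP dQTL scan
#'
#' Tests every supplied risk SNP against every supplied driver and adjusts
#' the full SNP x driver grid with Benjamini-Hochberg; significance is
#' Q < `q_threshold` (default 0.1). Risk SNPs absent from the genotypes are
#' reported and skipped.
#'
#' @param cohort a `Cohort`.
#' @param risk_snps character vector of risk SNP ids.
#' @param drivers driver ids to test (default all drivers in the cohort).
#' @param q_threshold BH significance cutoff (default 0.1).
#' @return `AssociationResult` data.frame with `q` filled in.
#' @export
scan_risk <- function(cohort, risk_snps, drivers = NULL, q_threshold = 0.1) {
  drivers <- drivers %||% colnames(cohort$drivers)
  missing <- setdiff(risk_snps, colnames(cohort$dosage))
  if (length(missing))
    warning("risk SNPs absent from genotypes, skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  snps <- intersect(risk_snps, colnames(cohort$dosage))
  if (!length(snps) || !length(drivers)) {
    warning("empty risk scan grid", call. = FALSE)
    return(.empty_results())
  }
  out <- do.call(rbind, lapply(drivers, function(d)
    .scan_snps(cohort, snps, d, "risk")))
  out$q <- p.adjust(out$p, method = "BH")
  out$threshold <- q_threshold
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out
}

#' Local dQTL scan with block-Bonferroni multiple testing
#'
#' Tests the MAF-filtered SNPs of a strategy's region set against one
#' driver. The per-SNP significance threshold is `alpha / n_blocks`, the
#' Bonferroni correction over haplotype blocks rather than SNPs.
#'
#' @param cohort a `Cohort`.
#' @param driver_id driver to test.
#' @param strategy `"linear"`, `"spatial"` or `"enhancer"` (label only;
#'   the caller chooses the region construction).
#' @param region_set the strategy's [region_set()].
#' @param block_set optional precomputed [gabriel_blocks()] over the
#'   scanned SNPs; computed here when `NULL`.
#' @param alpha block-Bonferroni family-wise level (default 0.1).
#' @param min_maf MAF filter (strict >, default 0.05).
#' @param ... passed to [gabriel_blocks()] when `block_set` is `NULL`.
#' @return list with `results` (`AssociationResult` rows), `block_set`,
#'   `threshold` and `n_blocks`. Zero scanned SNPs give an empty scan.
#' @export
scan_local <- function(cohort, driver_id,
                       strategy = c("linear", "spatial", "enhancer"),
                       region_set, block_set = NULL, alpha = 0.1,
                       min_maf = 0.05, ...) {
  strategy <- match.arg(strategy)
  snps <- maf_filter(cohort, min_maf,
                     snps_in_regions(cohort$snp_table, region_set))
  if (!length(snps))
    return(list(results = .empty_results(), block_set = NULL,
                threshold = NA_real_, n_blocks = 0L))
  if (is.null(block_set)) {
    st <- cohort$snp_table[match(snps, cohort$snp_table$id), , drop = FALSE]
    block_set <- gabriel_blocks(cohort$dosage, st, ...)
  }
  n_blocks <- count_tests(block_set)
  threshold <- alpha / n_blocks
  out <- .scan_snps(cohort, snps, driver_id, strategy)
  out$threshold <- threshold
  out$significant <- !is.na(out$p) & out$p < threshold
  list(results = out, block_set = block_set, threshold = threshold,
       n_blocks = n_blocks)
}

#' Select one tag SNP per significant haplotype block
#'
#' For each block containing at least one significant SNP, picks the SNP
#' with the minimum p-value; ties are broken by smaller genomic position.
#'
#' @param results `AssociationResult` rows (with `pos`).
#' @param block_set the [gabriel_blocks()] partition of the scanned SNPs.
#' @return subset of `results`, one row per tagged block, with a
#'   `block_index` column.
#' @export
select_tag_snps <- function(results, block_set) {
  rows <- list()
  for (b in seq_along(block_set$blocks)) {
    sub <- results[results$snp_id %in% block_set$blocks[[b]] &
                   results$significant %in% TRUE, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$p, sub$pos), , drop = FALSE]
    tag <- sub[1L, , drop = FALSE]
    tag$block_index <- b
    rows[[length(rows) + 1L]] <- tag
  }
  if (!length(rows)) {
    out <- .empty_results()
    out$block_index <- integer()
    return(out)
  }
  do.call(rbind, rows)
}

#' Index-event-bias adjustment
#'
#' Refits a discovered association adding the diagnosis-linked clinical
#' covariates: ISUP grade group (ordinal-coded 1-5), T category (binary,
#' >= T3) and log-PSA. Because every subject is a diagnosed case, selection
#' on these features can distort SNP-driver associations; an association
#' robust to this adjustment is less likely to be index-event bias.
#' Patients with missing clinical data are dropped (count reported);
#' a clinical covariate with a single observed level is dropped with a
#' warning.
#'
#' @param result one `AssociationResult` row.
#' @param cohort the `Cohort` the result came from.
#' @return the refitted `AssociationResult` row (strategy suffixed
#'   `"+clinical"`), with attribute `n_dropped`.
#' @export
index_event_adjustment <- function(result, cohort) {
  stopifnot(nrow(result) == 1L)
  cv <- cohort$covariates
  clin <- data.frame(isup = as.numeric(cv$ISUP_GG),
                     t3 = as.numeric(cv$T_category %in%
                                     c("T3", "T4", "T3a", "T3b")),
                     log_psa = log(cv$PSA))
  keep_cols <- vapply(clin, function(x)
    length(unique(x[!is.na(x)])) > 1L, logical(1))
  if (!all(keep_cols))
    warning("dropping degenerate clinical covariate(s): ",
            paste(names(clin)[!keep_cols], collapse = ", "), call. = FALSE)
  clin <- clin[, keep_cols, drop = FALSE]
  ok <- complete.cases(clin)
  meta <- cohort$driver_meta
  dtype <- meta$type[match(result$driver_id, meta$id)]
  out <- fit_driver_model(
    cohort$dosage[ok, result$snp_id],
    cohort$drivers[ok, result$driver_id],
    cv[ok, , drop = FALSE], driver_type = dtype,
    extra_covariates = as.matrix(clin[ok, , drop = FALSE]),
    snp_id = result$snp_id, driver_id = result$driver_id,
    strategy = paste0(result$strategy, "+clinical"))
  attr(out, "n_dropped") <- sum(!ok)
  out
}
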