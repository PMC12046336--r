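## Replication of discovered dQTLs, distal candidate screening, and
## random-effects meta-analysis of per-cohort log-odds estimates.

#' Test discovered dQTLs in a replication cohort
#'
#' Each discovered (SNP, driver) pair is refit in the replication cohort
#' with the same covariate model; Benjamini-Hochberg adjustment is applied
#' over the discovered set. A dQTL replicates when the replication effect
#' is sign-concordant with discovery and Q_replication < `q_threshold`.
#' When the replication cohort lacks CNA timing, discovery drivers are
#' matched by id (timing collapsed upstream by the caller via driver ids).
#'
#' @param discovered `AssociationResult` rows from discovery (must carry
#'   `beta`).
#' @param replication_cohort a `Cohort`.
#' @param q_threshold replication FDR cutoff (default 0.1).
#' @return data.frame of `ReplicationRecord`s: discovery and replication
#'   beta/se/p, `q_replication`, `concordant`, `replicated`, `testable`.
#' @export
test_replication <- function(discovered, replication_cohort,
                             q_threshold = 0.1) {
  n <- nrow(discovered)
  rec <- data.frame(
    snp_id = discovered$snp_id, driver_id = discovered$driver_id,
    beta_discovery = discovered$beta, se_discovery = discovered$se,
    p_discovery = discovered$p,
    beta_replication = NA_real_, se_replication = NA_real_,
    p_replication = NA_real_, q_replication = NA_real_,
    concordant = NA, replicated = NA, testable = FALSE,
    stringsAsFactors = FALSE)
  meta <- replication_cohort$driver_meta
  for (i in seq_len(n)) {
    s <- rec$snp_id[i]; d <- rec$driver_id[i]
    if (!s %in% colnames(replication_cohort$dosage) ||
        !d %in% colnames(replication_cohort$drivers)) next
    fit <- tryCatch(
      fit_driver_model(replication_cohort$dosage[, s],
                       replication_cohort$drivers[, d],
                       replication_cohort$covariates,
                       driver_type = meta$type[match(d, meta$id)],
                       snp_id = s, driver_id = d,
                       strategy = "replication"),
      error = function(e) NULL)
    if (is.null(fit) || is.na(fit$p)) next
    rec$testable[i] <- TRUE
    rec$beta_replication[i] <- fit$beta
    rec$se_replication[i] <- fit$se
    rec$p_replication[i] <- fit$p
  }
  t_idx <- which(rec$testable)
  rec$q_replication[t_idx] <- p.adjust(rec$p_replication[t_idx],
                                       method = "BH")
  rec$concordant <- sign(rec$beta_discovery) == sign(rec$beta_replication)
  rec$replicated <- rec$concordant %in% TRUE &
    !is.na(rec$q_replication) & rec$q_replication < q_threshold
  rec$replicated[!rec$testable] <- NA
  rec
}

#' Distal candidate screen of tag SNPs against all drivers
#'
#' Screens each (sign-concordant) tag SNP against every driver in a
#' candidate grid, BH-adjusted within the grid; the originating
#' (SNP, driver) pairs are excluded from candidacy.
#'
#' @param tag_snps character vector of tag SNP ids.
#' @param cohort a `Cohort`.
#' @param drivers driver ids to screen (default all).
#' @param originating optional data.frame `snp_id`, `driver_id` of the
#'   discovery pairs to exclude.
#' @param q_threshold candidate FDR cutoff (default 0.1).
#' @return `AssociationResult` rows with `q` and a `candidate` flag.
#' @export
distal_screen <- function(tag_snps, cohort, drivers = NULL,
                          originating = NULL, q_threshold = 0.1) {
  drivers <- drivers %||% colnames(cohort$drivers)
  out <- do.call(rbind, lapply(drivers, function(d)
    .scan_snps(cohort, tag_snps, d, "distal")))
  if (is.null(out)) return(.empty_results())
  if (!is.null(originating)) {
    orig <- paste(originating$snp_id, originating$driver_id)
    out <- out[!(paste(out$snp_id, out$driver_id) %in% orig), ,
               drop = FALSE]
  }
  out$q <- p.adjust(out$p, method = "BH")
  out$threshold <- q_threshold
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out$candidate <- out$significant
  out
}

## restricted log-likelihood of the random-effects model at tau2
.reml_loglik <- function(tau2, yi, vi) {
  w <- 1 / (vi + tau2)
  mu <- sum(w * yi) / sum(w)
  -0.5 * (sum(log(vi + tau2)) + log(sum(w)) + sum(w * (yi - mu)^2))
}

#' Random-effects meta-analysis by REML
#'
#' Combines per-cohort estimates under beta_i ~ Normal(mu, se_i^2 + tau^2).
#' The between-cohort variance tau^2 is estimated by restricted maximum
#' likelihood using Fisher-scoring iteration with nonnegativity projection
#' (tolerance 1e-8, max 100 iterations); the pooled effect is the
#' inverse-variance weighted mean at the converged tau^2, with Wald CI and
#' p-value.
#'
#' @param beta numeric vector of per-cohort effects (log-odds).
#' @param se positive standard errors (same length).
#' @param tau2_fixed optionally fix tau^2 (e.g. 0 for fixed-effect).
#' @return list of class `MetaResult`: `beta`, `se`, `tau2`, `ci95`
#'   (length 2), `p`, `k_studies`, `converged`.
#' @export
meta_analyze <- function(beta, se, tau2_fixed = NULL) {
  k <- length(beta)
  if (k == 0L) stop("meta_analyze requires k >= 1 estimates", call. = FALSE)
  stopifnot(length(se) == k, all(se > 0))
  vi <- se^2
  if (!is.null(tau2_fixed)) {
    tau2 <- tau2_fixed
    converged <- TRUE
  } else if (k == 1L) {
    tau2 <- 0
    converged <- TRUE
  } else {
    tau2 <- max(0, var(beta) - mean(vi))   # moment start
    converged <- FALSE
    for (it in 1:100) {
      w <- 1 / (vi + tau2)
      sw <- sum(w); sw2 <- sum(w^2); sw3 <- sum(w^3)
      mu <- sum(w * beta) / sw
      r2 <- (beta - mu)^2
      ## REML score and expected information in tau2
      score <- 0.5 * (sum(w^2 * r2) - sw + sw2 / sw)
      info <- 0.5 * (sw2 - 2 * sw3 / sw + (sw2 / sw)^2)
      if (info <= 0) break
      step <- score / info
      new <- max(0, tau2 + step)
      if (abs(new - tau2) < 1e-8) { tau2 <- new; converged <- TRUE; break }
      tau2 <- new
    }
    ## boundary solution: score negative at tau2 = 0 means the REML
    ## maximizer is the projection
    if (!converged && tau2 == 0) converged <- TRUE
  }
  w <- 1 / (vi + tau2)
  mu <- sum(w * beta) / sum(w)
  se_mu <- sqrt(1 / sum(w))
  z <- mu / se_mu
  out <- list(beta = mu, se = se_mu, tau2 = tau2,
              ci95 = c(mu - 1.959963984540054 * se_mu,
                       mu + 1.959963984540054 * se_mu),
              p = 2 * pnorm(-abs(z)), k_studies = k, converged = converged)
  class(out) <- "MetaResult"
  out
}

#' @export
print.MetaResult <- function(x, ...) {
  cat(sprintf(
    "MetaResult: beta=%.4f (se %.4f), tau2=%.5f, p=%.3g, k=%d\n",
    x$beta, x$se, x$tau2, x$p, x$k_studies))
  invisible(x)
}

#' Meta-analyze a set of dQTLs across cohorts
#'
#' Runs [meta_analyze()] per dQTL over the cohorts in which the driver is
#' callable (availability mask), then BH-adjusts across the dQTL set.
#'
#' @param estimates data.frame with `snp_id`, `driver_id`, `cohort`,
#'   `beta`, `se`; rows are (dQTL, cohort) estimates. Cohorts where a
#'   driver is not callable simply contribute no row.
#' @param q_threshold meta FDR cutoff (default 0.1).
#' @return data.frame: one row per dQTL with pooled `beta`, `se`, `tau2`,
#'   `p`, `q`, `k_studies`, `significant`.
#' @export
meta_analyze_set <- function(estimates, q_threshold = 0.1) {
  key <- paste(estimates$snp_id, estimates$driver_id, sep = "\r")
  keys <- unique(key)
  rows <- lapply(keys, function(k) {
    sub <- estimates[key == k, , drop = FALSE]
    m <- meta_analyze(sub$beta, sub$se)
    data.frame(snp_id = sub$snp_id[1L], driver_id = sub$driver_id[1L],
               beta = m$beta, se = m$se, tau2 = m$tau2, p = m$p,
               k_studies = m$k_studies, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$q) & out$q < q_threshold
  out
}
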