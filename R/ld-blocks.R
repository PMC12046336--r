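## Two-locus LD from unphased genotypes and Gabriel-style haplotype blocks.
## Blocks are the multiple-testing unit of the local dQTL scans.

## genotype-cell probabilities from haplotype freqs (p11, p10, p01, p00)
## cells indexed by (dosage1, dosage2) in 0..2
.cell_probs <- function(p11, p10, p01, p00) {
  m <- matrix(0, 3, 3)
  m[1, 1] <- p00^2
  m[1, 2] <- 2 * p00 * p01
  m[1, 3] <- p01^2
  m[2, 1] <- 2 * p00 * p10
  m[2, 2] <- 2 * (p11 * p00 + p10 * p01)
  m[2, 3] <- 2 * p01 * p11
  m[3, 1] <- p10^2
  m[3, 2] <- 2 * p10 * p11
  m[3, 3] <- p11^2
  m
}

## EM for two-locus haplotype frequencies from a 3x3 genotype count table.
## Returns freqs, final log-likelihood and the per-iteration trace.
.haplotype_em <- function(tab, tol = 1e-10, max_iter = 1000L) {
  n <- sum(tab)
  ## allele counts are fixed by the margins
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)        # alt freq locus 1
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  ## start from linkage equilibrium
  p11 <- pA * pB; p10 <- pA * (1 - pB); p01 <- (1 - pA) * pB
  p00 <- (1 - pA) * (1 - pB)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    cp <- .cell_probs(p11, p10, p01, p00)
    ll <- sum(tab[tab > 0] * log(cp[tab > 0]))
    ll_trace <- c(ll_trace, ll)
    ## E-step: only the double heterozygote cell is ambiguous
    denom <- p11 * p00 + p10 * p01
    w <- if (denom > 0) p11 * p00 / denom else 0.5
    ndh <- tab[2, 2]
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + w * ndh
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + (1 - w) * ndh
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + (1 - w) * ndh
    c00 <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2] + w * ndh
    tot <- c11 + c10 + c01 + c00
    new <- c(c11, c10, c01, c00) / tot
    delta <- max(abs(new - c(p11, p10, p01, p00)))
    p11 <- new[1]; p10 <- new[2]; p01 <- new[3]; p00 <- new[4]
    if (delta < tol) break
  }
  list(p = c(p11 = p11, p10 = p10, p01 = p01, p00 = p00),
       pA = pA, pB = pB, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace)
}

.dmax <- function(D, pA, pB) {
  if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
}

#' Two-locus LD from unphased diploid genotypes
#'
#' Estimates haplotype frequencies by EM from the 3 x 3 genotype table,
#' then D' = D / Dmax and r-squared, with a profile-likelihood confidence
#' interval for |D'| computed on a grid with allele frequencies held at
#' their (margin-determined) maximum-likelihood values — the construction
#' used by the Gabriel block definition.
#'
#' @param dosage_i,dosage_j dosage vectors in \{0, 1, 2, NA\}; individuals
#'   missing either genotype are excluded (complete-case).
#' @param conf confidence level for the |D'| interval (default 0.90).
#' @param grid_step grid resolution on |D'| in [0, 1] (default 0.005).
#' @return list of class `LDEstimate`: `d_prime`, `ci_low`, `ci_high`,
#'   `r2`, `n_informative`, `defined` (FALSE for monomorphic input).
#' @export
two_locus_ld <- function(dosage_i, dosage_j, conf = 0.90, grid_step = 0.005) {
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  di <- dosage_i[ok]; dj <- dosage_j[ok]
  n <- length(di)
  und <- structure(list(d_prime = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, r2 = NA_real_,
                        n_informative = n, defined = FALSE),
                   class = "LDEstimate")
  if (n == 0L) return(und)
  tab <- matrix(0, 3, 3)
  for (k in seq_len(n)) tab[di[k] + 1L, dj[k] + 1L] <-
      tab[di[k] + 1L, dj[k] + 1L] + 1
  em <- .haplotype_em(tab)
  if (em$pA <= 0 || em$pA >= 1 || em$pB <= 0 || em$pB >= 1) return(und)
  D <- em$p["p11"] - em$pA * em$pB
  names(D) <- NULL
  dmx <- .dmax(D, em$pA, em$pB)
  d_prime <- if (dmx > 0) abs(D) / dmx else 0
  d_prime <- min(d_prime, 1)
  denom <- em$pA * (1 - em$pA) * em$pB * (1 - em$pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  ## profile likelihood over |D'| in the direction of the point estimate
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = grid_step)
  dmax_dir <- .dmax(sgn, em$pA, em$pB)  # Dmax for the chosen sign
  ll <- vapply(grid, function(dp) {
    Dg <- sgn * dp * dmax_dir
    p11 <- em$pA * em$pB + Dg
    p10 <- em$pA * (1 - em$pB) - Dg
    p01 <- (1 - em$pA) * em$pB - Dg
    p00 <- (1 - em$pA) * (1 - em$pB) + Dg
    eps <- 1e-12
    cp <- .cell_probs(max(p11, eps), max(p10, eps), max(p01, eps),
                      max(p00, eps))
    sum(tab[tab > 0] * log(cp[tab > 0]))
  }, numeric(1))
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  a <- (1 - conf) / 2
  ci_low <- grid[which(cum >= a)[1L]]
  ci_high <- grid[which(cum >= 1 - a)[1L]]
  structure(list(d_prime = d_prime, ci_low = ci_low, ci_high = ci_high,
                 r2 = r2, n_informative = n, defined = TRUE),
            class = "LDEstimate")
}

#' @export
print.LDEstimate <- function(x, ...) {
  if (!x$defined) cat("LDEstimate: undefined (monomorphic locus)\n")
  else cat(sprintf("LDEstimate: D'=%.3f [%.3f, %.3f], r2=%.3f, n=%d\n",
                   x$d_prime, x$ci_low, x$ci_high, x$r2, x$n_informative))
  invisible(x)
}

#' Haplotype blocks by the Gabriel definition
#'
#' Classifies SNP pairs as "strong LD" (|D'| CI lower bound >= `strong_low`
#' and upper bound >= `strong_high`) or "strong recombination" (upper bound
#' < `recomb_high`); pairs with fewer than `min_informative` complete
#' genotypes, or falling in neither class, are uninformative. A contiguous
#' candidate block is accepted when it has at least one informative pair
#' and at least `strong_fraction` of its informative pairs are strong LD.
#' Overlapping candidates are resolved greedily, longest first (ties to the
#' leftmost start); SNPs in no accepted block become singleton blocks.
#'
#' @param dosage patients x SNPs matrix (columns named by SNP id).
#' @param snp_table data.frame with `id`, `chrom`, `pos` for the SNPs to
#'   partition (subset and order define the genomic order).
#' @param strong_low,strong_high,recomb_high,strong_fraction Gabriel
#'   thresholds (defaults 0.70, 0.98, 0.90, 0.95).
#' @param min_informative minimum complete genotypes per pair (default 20).
#' @param conf CI level passed to [two_locus_ld()] (default 0.90).
#' @param max_span_snps compute LD only for pairs at most this many SNPs
#'   apart (default `Inf`); candidate blocks are capped accordingly.
#' @return object of class `HaplotypeBlockSet`: `blocks` (list of SNP-id
#'   vectors in genomic order), `strong_fraction` per block, `snp_ids`.
#' @export
gabriel_blocks <- function(dosage, snp_table, strong_low = 0.70,
                           strong_high = 0.98, recomb_high = 0.90,
                           strong_fraction = 0.95, min_informative = 20L,
                           conf = 0.90, max_span_snps = Inf) {
  stopifnot(nrow(snp_table) >= 1L)
  ord <- order(snp_table$chrom, snp_table$pos)
  st <- snp_table[ord, , drop = FALSE]
  ids <- st$id
  m <- length(ids)
  if (m == 1L) {
    out <- list(blocks = list(ids), strong_fraction = NA_real_,
                snp_ids = ids)
    class(out) <- "HaplotypeBlockSet"
    return(out)
  }
  ## pair classification: 1 = strong LD, -1 = strong recomb, 0 = uninformative
  cls <- matrix(0L, m, m)
  for (i in seq_len(m - 1L)) {
    jmax <- min(m, i + max_span_snps)
    for (j in (i + 1L):jmax) {
      if (st$chrom[i] != st$chrom[j]) next
      ld <- two_locus_ld(dosage[, ids[i]], dosage[, ids[j]], conf = conf)
      if (!ld$defined || ld$n_informative < min_informative) next
      if (ld$ci_low >= strong_low && ld$ci_high >= strong_high)
        cls[i, j] <- 1L
      else if (ld$ci_high < recomb_high) cls[i, j] <- -1L
    }
  }
  ## candidate blocks: all contiguous runs on one chromosome
  cand <- list()
  for (i in seq_len(m - 1L)) {
    jmax <- min(m, i + max_span_snps)
    for (j in (i + 1L):jmax) {
      if (st$chrom[i] != st$chrom[j]) break
      sub <- cls[i:j, i:j]
      n_strong <- sum(sub == 1L)
      n_inf <- n_strong + sum(sub == -1L)
      if (n_inf >= 1L && n_strong / n_inf >= strong_fraction)
        cand[[length(cand) + 1L]] <-
          list(i = i, j = j, frac = n_strong / n_inf)
    }
  }
  covered <- rep(FALSE, m)
  blocks <- list(); fracs <- numeric(0)
  if (length(cand)) {
    len <- vapply(cand, function(b) b$j - b$i + 1L, integer(1))
    left <- vapply(cand, `[[`, integer(1), "i")
    for (k in order(-len, left)) {
      b <- cand[[k]]
      if (any(covered[b$i:b$j])) next
      covered[b$i:b$j] <- TRUE
      blocks[[length(blocks) + 1L]] <- ids[b$i:b$j]
      fracs <- c(fracs, b$frac)
    }
  }
  for (i in which(!covered)) {
    blocks[[length(blocks) + 1L]] <- ids[i]
    fracs <- c(fracs, NA_real_)
  }
  ## order blocks by genomic position of their first SNP
  first <- vapply(blocks, function(b) match(b[1L], ids), integer(1))
  o <- order(first)
  out <- list(blocks = blocks[o], strong_fraction = fracs[o], snp_ids = ids)
  class(out) <- "HaplotypeBlockSet"
  out
}

#' @export
print.HaplotypeBlockSet <- function(x, ...) {
  sizes <- lengths(x$blocks)
  cat(sprintf("HaplotypeBlockSet: %d block(s) over %d SNPs (median size %g)\n",
              length(x$blocks), length(x$snp_ids), median(sizes)))
  invisible(x)
}

#' Number of haplotype blocks (multiple-testing denominator)
#'
#' The per-driver, per-strategy Bonferroni denominator of the local scans.
#'
#' @param block_set a [gabriel_blocks()] result.
#' @return integer block count.
#' @export
count_tests <- function(block_set) {
  stopifnot(inherits(block_set, "HaplotypeBlockSet"))
  length(block_set$blocks)
}
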