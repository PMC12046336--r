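## Independent reference implementations used as test oracles. These stay
## deliberately naive (recurrences, enumeration, brute force) and never
## share code with the package paths they check.

## hypergeometric pmf over its whole support via the ratio recurrence
## P(k+1)/P(k) = (K-k)(n-k) / ((k+1)(N-K-n+k+1)), normalized; independent
## of R's phyper/dhyper C code
oracle_hyper_pmf <- function(N, K, n) {
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  pmf <- numeric(hi - lo + 1L)
  pmf[1L] <- 1
  if (hi > lo) for (k in lo:(hi - 1L)) {
    r <- (K - k) * (n - k) / ((k + 1) * (N - K - n + k + 1))
    pmf[k - lo + 2L] <- pmf[k - lo + 1L] * r
  }
  pmf <- pmf / sum(pmf)
  names(pmf) <- lo:hi
  pmf
}

oracle_hyper_upper <- function(N, K, n, k) {
  pmf <- oracle_hyper_pmf(N, K, n)
  sum(pmf[as.integer(names(pmf)) >= k])
}

oracle_hyper_lower <- function(N, K, n, k) {
  pmf <- oracle_hyper_pmf(N, K, n)
  sum(pmf[as.integer(names(pmf)) <= k])
}

## two-sided Fisher exact p by table enumeration over the hypergeometric
## support, summing probabilities <= observed (with the 1 + 1e-7 relative
## tolerance convention)
oracle_fisher_two_sided <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + b; n <- a + c
  pmf <- oracle_hyper_pmf(N, K, n)
  p_obs <- pmf[as.character(a)]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

## from-scratch Newton-Raphson logistic regression (no glm.fit)
oracle_logistic <- function(X, y, tol = 1e-12, max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    mu <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- mu * (1 - mu)
    step <- solve(crossprod(X, X * W), crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  mu <- 1 / (1 + exp(-drop(X %*% beta)))
  cov <- solve(crossprod(X, X * (mu * (1 - mu))))
  list(beta = beta, se = sqrt(diag(cov)))
}

## brute-force SNP-in-interval membership (O(n * m) scan)
oracle_snps_in_regions <- function(snp_table, intervals) {
  hit <- vapply(seq_len(nrow(snp_table)), function(i) {
    any(intervals$chrom == snp_table$chrom[i] &
        intervals$start <= snp_table$pos[i] &
        intervals$end >= snp_table$pos[i])
  }, logical(1))
  s <- snp_table[hit, , drop = FALSE]
  s$id[order(s$chrom, s$pos)]
}

## exhaustive enhancer-rule partner enumeration on a toy anchor table
oracle_enhancer_partners <- function(pairs, drv) {
  ov <- function(s, e) s <= drv$end & e >= drv$start &
    rep(TRUE, length(s))
  hit_a <- pairs$chrom_a == drv$chrom & ov(pairs$start_a, pairs$end_a)
  hit_b <- pairs$chrom_b == drv$chrom & ov(pairs$start_b, pairs$end_b)
  keep_b <- pairs[hit_a & !hit_b, c("chrom_b", "start_b", "end_b")]
  keep_a <- pairs[hit_b & !hit_a, c("chrom_a", "start_a", "end_a")]
  names(keep_b) <- names(keep_a) <- c("chrom", "start", "end")
  out <- rbind(keep_b, keep_a)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

## exhaustive Gabriel reference: classify all pairs with the package's LD
## estimator (shared measurement, independent partition logic), enumerate
## every contiguous candidate, apply the 95% rule, resolve greedily
oracle_gabriel_partition <- function(dosage, snp_table,
                                     min_informative = 20) {
  ord <- order(snp_table$chrom, snp_table$pos)
  st <- snp_table[ord, ]
  m <- nrow(st)
  strong <- recomb <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (st$chrom[i] != st$chrom[j]) next
    ld <- two_locus_ld(dosage[, st$id[i]], dosage[, st$id[j]])
    if (!ld$defined || ld$n_informative < min_informative) next
    if (ld$ci_low >= 0.70 && ld$ci_high >= 0.98) strong[i, j] <- TRUE
    else if (ld$ci_high < 0.90) recomb[i, j] <- TRUE
  }
  cands <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (st$chrom[i] != st$chrom[j]) next
    ns <- sum(strong[i:j, i:j]); nr <- sum(recomb[i:j, i:j])
    if (ns + nr >= 1 && ns / (ns + nr) >= 0.95)
      cands[[length(cands) + 1]] <- c(i, j)
  }
  taken <- rep(FALSE, m)
  blocks <- list()
  if (length(cands)) {
    sizes <- vapply(cands, function(x) x[2] - x[1] + 1, numeric(1))
    lefts <- vapply(cands, `[`, numeric(1), 1)
    for (k in order(-sizes, lefts)) {
      b <- cands[[k]]
      if (any(taken[b[1]:b[2]])) next
      taken[b[1]:b[2]] <- TRUE
      blocks[[length(blocks) + 1]] <- st$id[b[1]:b[2]]
    }
  }
  for (i in which(!taken)) blocks[[length(blocks) + 1]] <- st$id[i]
  first <- vapply(blocks, function(b) match(b[1], st$id), numeric(1))
  blocks[order(first)]
}

## restricted likelihood grid maximizer for the random-effects model
oracle_reml_tau2 <- function(yi, vi, grid = seq(0, 2, 1e-4)) {
  ll <- vapply(grid, function(t) {
    w <- 1 / (vi + t)
    mu <- sum(w * yi) / sum(w)
    -0.5 * (sum(log(vi + t)) + log(sum(w)) + sum(w * (yi - mu)^2))
  }, numeric(1))
  grid[which.max(ll)]
}

## Monte Carlo power of the allelic chi-square test (vectorized over sims)
oracle_mc_power <- function(maf, or_, n_total, driver_frequency, alpha,
                            n_sim = 20000, seed = 1) {
  set.seed(seed)
  n_case <- round(n_total * driver_frequency)
  n_control <- n_total - n_case
  q <- uniroot(function(q) {
    pc <- or_ * q / (1 - q + or_ * q)
    driver_frequency * pc + (1 - driver_frequency) * q - maf
  }, c(1e-9, 1 - 1e-9))$root
  p_case <- or_ * q / (1 - q + or_ * q)
  a <- rbinom(n_sim, 2 * n_case, p_case)
  b <- rbinom(n_sim, 2 * n_control, q)
  phat <- (a + b) / (2 * n_total)
  num <- (a / (2 * n_case) - b / (2 * n_control))^2
  den <- phat * (1 - phat) * (1 / (2 * n_case) + 1 / (2 * n_control))
  stat <- ifelse(den > 0, num / den, 0)
  mean(stat > qchisq(1 - alpha, 1))
}
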