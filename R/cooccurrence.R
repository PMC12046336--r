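## Pairwise somatic driver co-occurrence / mutual exclusivity by
## hypergeometric tests, the extreme-case minimum achievable p-value, and
## the minimum cohort size needed to detect exclusivity.

## inclusive hypergeometric tails for k co-mutated out of N patients with
## K carrying driver a and n carrying driver b
.hyper_tails <- function(N, K, n, k) {
  list(cooccur = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       exclusive = phyper(k, K, N - K, n))
}

#' Pairwise driver co-occurrence / mutual exclusivity tests
#'
#' For every pair of drivers present in at least `min_patients` patients,
#' computes the inclusive upper-tail hypergeometric p for co-occurrence
#' and the inclusive lower-tail p for mutual exclusivity, BH-adjusts each
#' direction separately, and classifies pairs at Q < `q_threshold`. Each
#' pair also carries its minimum achievable p (extreme case) and a
#' `powered` flag (min p < `q_threshold`).
#'
#' @param driver_matrix patients x drivers binary matrix.
#' @param min_patients minimum driver prevalence in patients (default 15).
#' @param q_threshold classification cutoff (default 0.05).
#' @param joint_adjust BH over both directions jointly instead of per
#'   direction (default `FALSE`).
#' @return data.frame of `PairResult`s: `driver_a`, `driver_b`, `N`, `K`,
#'   `n`, `k`, `p_cooccur`, `p_exclusive`, `q_cooccur`, `q_exclusive`,
#'   `direction` (`"cooccur"`, `"exclusive"` or `NA`), `min_p_cooccur`,
#'   `min_p_exclusive`, `powered_cooccur`, `powered_exclusive`.
#' @export
pairwise_tests <- function(driver_matrix, min_patients = 15L,
                           q_threshold = 0.05, joint_adjust = FALSE) {
  stopifnot(all(driver_matrix %in% c(0L, 1L, NA)))
  counts <- colSums(driver_matrix, na.rm = TRUE)
  keep <- names(counts)[counts >= min_patients]
  if (length(keep) < 2L) return(NULL)
  combs <- utils::combn(keep, 2L)
  N <- nrow(driver_matrix)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    K <- sum(driver_matrix[, a], na.rm = TRUE)
    n <- sum(driver_matrix[, b], na.rm = TRUE)
    k <- sum(driver_matrix[, a] * driver_matrix[, b], na.rm = TRUE)
    tails <- .hyper_tails(N, K, n, k)
    data.frame(driver_a = a, driver_b = b, N = N, K = K, n = n, k = k,
               p_cooccur = tails$cooccur, p_exclusive = tails$exclusive,
               min_p_cooccur = extreme_case_p(N, K, n, "cooccur"),
               min_p_exclusive = extreme_case_p(N, K, n, "exclusive"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (joint_adjust) {
    q <- p.adjust(c(out$p_cooccur, out$p_exclusive), method = "BH")
    out$q_cooccur <- q[seq_len(nrow(out))]
    out$q_exclusive <- q[-seq_len(nrow(out))]
  } else {
    out$q_cooccur <- p.adjust(out$p_cooccur, method = "BH")
    out$q_exclusive <- p.adjust(out$p_exclusive, method = "BH")
  }
  out$direction <- ifelse(out$q_cooccur < q_threshold, "cooccur",
                          ifelse(out$q_exclusive < q_threshold,
                                 "exclusive", NA_character_))
  out$powered_cooccur <- out$min_p_cooccur < q_threshold
  out$powered_exclusive <- out$min_p_exclusive < q_threshold
  out
}

#' Minimum achievable p-value for a driver pair
#'
#' The p-value of the most extreme configuration given the observed
#' marginal counts: zero co-mutated patients for exclusivity, or all
#' patients with the rarer driver also carrying the more frequent one for
#' co-occurrence.
#'
#' @param N cohort size; `K`, `n` marginal driver counts (`<= N`).
#' @param direction `"exclusive"` or `"cooccur"`.
#' @return the minimum achievable p.
#' @export
extreme_case_p <- function(N, K, n, direction = c("exclusive", "cooccur")) {
  direction <- match.arg(direction)
  stopifnot(K <= N, n <= N)
  if (direction == "exclusive") phyper(0, K, N - K, n)
  else phyper(min(K, n) - 1, K, N - K, n, lower.tail = FALSE)
}

#' Minimum cohort size to detect mutual exclusivity
#'
#' Smallest integer N such that the extreme case (zero co-mutated
#' patients) is significant at `alpha`, with driver counts K = round(
#' freq_a N), n = round(freq_b N). Found by monotone search.
#'
#' @param freq_a,freq_b driver frequencies in (0, 1).
#' @param alpha significance level (default 0.05).
#' @param n_cap search cap (default 1e6); exceeding it is an error.
#' @return smallest qualifying N.
#' @export
min_cohort_for_exclusivity <- function(freq_a, freq_b, alpha = 0.05,
                                       n_cap = 1e6L) {
  .assert_prob(c(freq_a, freq_b), "frequencies")
  .assert_prob(alpha, "alpha")
  N <- 2L
  repeat {
    K <- round(freq_a * N); n <- round(freq_b * N)
    if (K >= 1 && n >= 1 && K <= N && n <= N &&
        extreme_case_p(N, K, n, "exclusive") < alpha) return(N)
    N <- N + 1L
    if (N > n_cap)
      stop(sprintf("no N <= %d reaches alpha = %g", n_cap, alpha),
           call. = FALSE)
  }
}
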