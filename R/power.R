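## Analytic power for dQTL detection via the non-centrality parameter of
## the 1-df chi-square allelic test, power grids, and extrapolation of the
## number of undiscovered dQTLs.

## Solve case/control alt-allele frequencies from the population frequency
## and the per-allele odds ratio. With case fraction phi:
##   p_case = OR q / (1 - q + OR q),  phi p_case + (1 - phi) q = maf
## which is a quadratic in the control frequency q.
.case_control_freqs <- function(maf, or_, phi) {
  if (or_ == 1) return(list(p_case = maf, p_control = maf))
  ## expand: phi*OR*q + (1-phi) q (1 - q + OR q) = maf (1 - q + OR q)
  a <- (1 - phi) * (or_ - 1)
  b <- phi * or_ + (1 - phi) - maf * (or_ - 1)
  cc <- -maf
  disc <- b^2 - 4 * a * cc
  q <- (-b + sqrt(disc)) / (2 * a)
  p_case <- or_ * q / (1 - q + or_ * q)
  list(p_case = p_case, p_control = q)
}

#' Analytic power for a dQTL association
#'
#' Power of the 1-df allelic chi-square test under the alternative, based
#' on its non-centrality parameter. Case/control allele frequencies are
#' solved exactly from the per-allele odds ratio and the population minor
#' allele frequency; NCP = (p_case - p_control)^2 / [pbar (1 - pbar)
#' (1/(2 n_case) + 1/(2 n_control))] with pbar the population frequency.
#' The fitted scan is a genotype-based logistic model, so this is an
#' approximation; the Monte Carlo oracle in the test-suite quantifies the
#' gap.
#'
#' @param maf population minor allele frequency in (0, 0.5].
#' @param or_ per-allele odds ratio (> 0).
#' @param n_total total cohort size.
#' @param driver_frequency case fraction in (0, 1).
#' @param alpha significance level.
#' @return power in [0, 1]; exactly `alpha` when `or_ = 1`.
#' @export
analytic_power <- function(maf, or_, n_total, driver_frequency, alpha) {
  stopifnot(maf > 0, maf <= 0.5, or_ > 0, n_total > 0)
  .assert_prob(driver_frequency, "driver_frequency")
  .assert_prob(alpha, "alpha")
  n_case <- n_total * driver_frequency
  n_control <- n_total * (1 - driver_frequency)
  fr <- .case_control_freqs(maf, or_, driver_frequency)
  pbar <- maf
  ncp <- (fr$p_case - fr$p_control)^2 /
    (pbar * (1 - pbar) * (1 / (2 * n_case) + 1 / (2 * n_control)))
  crit <- qchisq(1 - alpha, df = 1)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}

#' Power surface over MAF x OR x driver-frequency grids
#'
#' @param maf_grid,or_grid,freq_grid grid vectors.
#' @param n total cohort size.
#' @param alpha significance level.
#' @return list with `power` (3-d array maf x or x freq) and
#'   `max_by_freq`, the per-driver-frequency maximum over MAF per OR.
#' @export
power_grid <- function(maf_grid, or_grid, freq_grid, n, alpha) {
  arr <- array(NA_real_, dim = c(length(maf_grid), length(or_grid),
                                 length(freq_grid)),
               dimnames = list(maf = maf_grid, or = or_grid,
                               freq = freq_grid))
  for (i in seq_along(maf_grid))
    for (j in seq_along(or_grid))
      for (k in seq_along(freq_grid))
        arr[i, j, k] <- analytic_power(maf_grid[i], or_grid[j], n,
                                       freq_grid[k], alpha)
  list(power = arr, max_by_freq = apply(arr, c(3, 2), max))
}

#' Extrapolate the number of undiscovered dQTLs
#'
#' Discovered dQTLs are binned on (MAF, OR, driver frequency); per bin the
#' expected total is observed / mean power and the undiscovered count is
#' the excess over observed, floored at 0. Bins whose mean power falls
#' below `power_floor` are excluded with a warning to avoid explosion.
#'
#' @param discovered data.frame with `maf`, `or_`, `driver_freq` of the
#'   discovered dQTLs.
#' @param n cohort size the discoveries came from.
#' @param alpha discovery significance level.
#' @param maf_breaks,or_breaks,freq_breaks bin boundaries.
#' @param power_floor minimum usable mean bin power (default 0.01).
#' @return list with `undiscovered` (expected additional count), `total`
#'   (expected universe size) and the per-bin table.
#' @export
extrapolate_undiscovered <- function(discovered, n, alpha,
                                     maf_breaks = c(0, 0.1, 0.2, 0.35, 0.5),
                                     or_breaks = c(1, 1.5, 2, 3, Inf),
                                     freq_breaks = c(0, 0.1, 0.25, 1),
                                     power_floor = 0.01) {
  stopifnot(nrow(discovered) > 0)
  or_eff <- pmax(discovered$or_, 1 / discovered$or_)  # symmetric in effect
  bin <- paste(
    cut(discovered$maf, maf_breaks, include.lowest = TRUE),
    cut(or_eff, or_breaks, include.lowest = TRUE),
    cut(discovered$driver_freq, freq_breaks, include.lowest = TRUE))
  pow <- vapply(seq_len(nrow(discovered)), function(i)
    analytic_power(discovered$maf[i], or_eff[i], n,
                   discovered$driver_freq[i], alpha), numeric(1))
  tab <- do.call(rbind, lapply(unique(bin), function(b) {
    idx <- bin == b
    data.frame(bin = b, observed = sum(idx), mean_power = mean(pow[idx]),
               stringsAsFactors = FALSE)
  }))
  low <- tab$mean_power < power_floor
  if (any(low))
    warning(sprintf("%d bin(s) below power floor %.3g excluded",
                    sum(low), power_floor), call. = FALSE)
  tab <- tab[!low, , drop = FALSE]
  tab$expected <- tab$observed / tab$mean_power
  tab$undiscovered <- pmax(0, tab$expected - tab$observed)
  list(undiscovered = sum(tab$undiscovered),
       total = sum(tab$expected), bins = tab)
}
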