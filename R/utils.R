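#' @importFrom stats p.adjust qnorm rbinom runif rnorm plogis pchisq
#'   qchisq dhyper phyper fisher.test glm.fit binomial coef lm AIC
#'   complete.cases pnorm sd var median smooth.spline predict rpois
#' @importFrom utils read.table write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a per-stage seed from a global seed
#'
#' One global seed fans out deterministically to per-stage seeds so that
#' individual pipeline stages are reproducible even when other stages are
#' toggled off. The derivation keeps seeds in the 32-bit integer range.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

## strictly-positive finite check used across modules
.assert_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open) x > 0 & x < 1 else x >= 0 & x <= 1)
  if (!all(ok)) stop(sprintf("'%s' must lie in %s", name,
                             if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

#' Rank inverse-normal transform
#'
#' Maps a numeric vector to normal scores via its ranks (Blom-type offset
#' 0.5). Invariant to any strictly monotone transform of the input; ties
#' share the average rank. Used for expression traits before QTL fitting.
#'
#' @param x numeric vector (NAs preserved).
#' @return numeric vector of normal scores.
#' @export
rank_inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

## minor allele frequency from a dosage column in {0,1,2,NA}
.maf_from_dosage <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

## alt-allele frequency (not folded)
.aaf_from_dosage <- function(d) {
  d <- d[!is.na(d)]
  if (!length(d)) return(NA_real_)
  sum(d) / (2 * length(d))
}
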