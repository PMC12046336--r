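## SNP search-space construction for the four dQTL discovery strategies.
## All coordinates are 1-based inclusive; overlap means >= 1 shared base.

#' Construct a RegionSet
#'
#' A RegionSet is a provenance-labeled set of genomic intervals (1-based
#' inclusive) defining the SNP search space for one somatic driver under one
#' discovery strategy. Overlapping intervals are merged so the set is a
#' disjoint union.
#'
#' @param chrom,start,end interval vectors (1-based inclusive).
#' @param strategy one of `"risk"`, `"linear"`, `"spatial"`, `"enhancer"`.
#' @param driver_id driver identifier the set belongs to (optional).
#' @param merge merge overlapping/adjacent-overlapping intervals (default).
#' @return an object of class `RegionSet` with elements `intervals`
#'   (data.frame `chrom`, `start`, `end`, sorted), `strategy`, `driver_id`.
#' @export
region_set <- function(chrom, start, end,
                       strategy = c("linear", "risk", "spatial", "enhancer"),
                       driver_id = NA_character_, merge = TRUE) {
  strategy <- match.arg(strategy)
  if (length(chrom) && any(end < start))
    stop("RegionSet requires start <= end", call. = FALSE)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (merge) gr <- GenomicRanges::reduce(gr)
  gr <- GenomicRanges::sort(gr)
  out <- list(
    intervals = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr), stringsAsFactors = FALSE),
    strategy = strategy,
    driver_id = if (length(driver_id)) driver_id[1L] else NA_character_)
  class(out) <- "RegionSet"
  out
}

#' @export
print.RegionSet <- function(x, ...) {
  cat(sprintf("RegionSet <%s> driver=%s: %d interval(s), %s bp\n",
              x$strategy, x$driver_id, nrow(x$intervals),
              format(sum(x$intervals$end - x$intervals$start + 1),
                     big.mark = ",")))
  invisible(x)
}

.rs_granges <- function(rs) {
  GenomicRanges::GRanges(rs$intervals$chrom,
                         IRanges::IRanges(rs$intervals$start,
                                          rs$intervals$end))
}

#' Construct a LoopAnchorSet
#'
#' Paired chromatin-loop anchors (e.g. from ChIA-PET or HiChIP), labeled by
#' cell line and ChIP target. Coordinates are 1-based inclusive.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b anchor intervals.
#' @param cell_line,target label vectors (recycled).
#' @return object of class `LoopAnchorSet` with a `pairs` data.frame.
#' @export
loop_anchor_set <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b,
                            cell_line, target) {
  n <- length(chrom_a)
  if (n && (any(end_a < start_a) || any(end_b < start_b)))
    stop("anchor with end < start", call. = FALSE)
  out <- list(pairs = data.frame(
    chrom_a = as.character(chrom_a), start_a = as.integer(start_a),
    end_a = as.integer(end_a), chrom_b = as.character(chrom_b),
    start_b = as.integer(start_b), end_b = as.integer(end_b),
    cell_line = rep_len(as.character(cell_line), n),
    target = rep_len(as.character(target), n), stringsAsFactors = FALSE))
  class(out) <- "LoopAnchorSet"
  out
}

#' @export
print.LoopAnchorSet <- function(x, ...) {
  cat(sprintf("LoopAnchorSet: %d pair(s); cell lines: %s; targets: %s\n",
              nrow(x$pairs),
              paste(unique(x$pairs$cell_line), collapse = ","),
              paste(unique(x$pairs$target), collapse = ",")))
  invisible(x)
}

## anchor pairs as two parallel GRanges
.anchors_granges <- function(anchors, side = c("a", "b")) {
  side <- match.arg(side)
  p <- anchors$pairs
  if (side == "a")
    GenomicRanges::GRanges(p$chrom_a, IRanges::IRanges(p$start_a, p$end_a))
  else
    GenomicRanges::GRanges(p$chrom_b, IRanges::IRanges(p$start_b, p$end_b))
}

#' Linear search window around a driver region
#'
#' The linear-local strategy tests SNPs within a flanking window on either
#' side of the somatic event boundaries (default +/- 500 kbp). The window is
#' clipped at position 1 and, when `chrom_lengths` is supplied, at the
#' chromosome end.
#'
#' @param driver_region a [region_set()] (or data.frame with `chrom`,
#'   `start`, `end`) giving the driver's defining interval(s).
#' @param flank flank size in bp (default 500,000).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-clipping; unknown chromosomes are an error when supplied.
#' @return a `RegionSet` with strategy `"linear"`.
#' @export
linear_window <- function(driver_region, flank = 5e5, chrom_lengths = NULL) {
  stopifnot(flank >= 0)
  iv <- if (inherits(driver_region, "RegionSet")) driver_region$intervals
        else as.data.frame(driver_region)
  drv <- if (inherits(driver_region, "RegionSet")) driver_region$driver_id
         else NA_character_
  start <- pmax(1, iv$start - flank)
  end <- iv$end + flank
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(iv$chrom, names(chrom_lengths))
    if (length(unknown))
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    end <- pmin(end, chrom_lengths[iv$chrom])
  }
  region_set(iv$chrom, start, end, strategy = "linear", driver_id = drv)
}

#' Spatial search regions from chromatin-loop anchors
#'
#' Implements the spatial-local strategy: for every loop with one anchor
#' overlapping the driver region, the partner anchor is a candidate distal
#' region. Candidate partner intervals are merged per cell line, then only
#' merged intervals supported by at least `min_cell_lines` distinct cell
#' lines are kept; finally the exclusion set (by construction the linear
#' window, so spatial regions lie outside it) is subtracted.
#'
#' @param driver_region a [region_set()] for the driver.
#' @param anchor_sets a [loop_anchor_set()] or list of them (concatenated).
#' @param min_cell_lines minimum distinct cell-line support (default 2).
#' @param exclude optional `RegionSet` to subtract (typically
#'   `linear_window(driver_region)`).
#' @return a `RegionSet` with strategy `"spatial"` (possibly empty).
#' @export
spatial_regions <- function(driver_region, anchor_sets, min_cell_lines = 2,
                            exclude = NULL) {
  stopifnot(min_cell_lines >= 1)
  anchors <- .bind_anchor_sets(anchor_sets)
  drv_gr <- .rs_granges(driver_region)
  p <- anchors$pairs
  if (!nrow(p))
    return(region_set(character(), integer(), integer(),
                      strategy = "spatial",
                      driver_id = driver_region$driver_id))
  ga <- .anchors_granges(anchors, "a")
  gb <- .anchors_granges(anchors, "b")
  hit_a <- GenomicRanges::countOverlaps(ga, drv_gr) > 0
  hit_b <- GenomicRanges::countOverlaps(gb, drv_gr) > 0
  ## partner anchors of loops touching the driver (either orientation)
  partners <- c(gb[hit_a], ga[hit_b])
  cells <- c(p$cell_line[hit_a], p$cell_line[hit_b])
  if (!length(partners))
    return(region_set(character(), integer(), integer(),
                      strategy = "spatial",
                      driver_id = driver_region$driver_id))
  ## merge all partners, then count distinct supporting cell lines per merged
  ## interval: overlapping partners from different cell lines accumulate
  merged <- GenomicRanges::reduce(partners)
  ov <- GenomicRanges::findOverlaps(merged, partners)
  support <- tapply(cells[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(x) length(unique(x)))
  keep_idx <- as.integer(names(support))[support >= min_cell_lines]
  kept <- merged[sort(keep_idx)]
  if (!is.null(exclude) && length(kept))
    kept <- GenomicRanges::setdiff(kept, .rs_granges(exclude))
  region_set(as.character(GenomeInfoDb::seqnames(kept)),
             GenomicRanges::start(kept), GenomicRanges::end(kept),
             strategy = "spatial", driver_id = driver_region$driver_id)
}

#' Enhancer search regions from HiChIP anchor pairs
#'
#' Keeps partner anchors of loops where exactly one anchor overlaps the
#' driver region (pairs fully inside the driver region contribute nothing).
#' A single cell line suffices, unlike [spatial_regions()].
#'
#' @param driver_region a [region_set()] for the driver.
#' @param hichip_anchors a [loop_anchor_set()].
#' @return a `RegionSet` with strategy `"enhancer"`.
#' @export
enhancer_regions <- function(driver_region, hichip_anchors) {
  anchors <- .bind_anchor_sets(hichip_anchors)
  drv_gr <- .rs_granges(driver_region)
  if (!nrow(anchors$pairs))
    return(region_set(character(), integer(), integer(),
                      strategy = "enhancer",
                      driver_id = driver_region$driver_id))
  ga <- .anchors_granges(anchors, "a")
  gb <- .anchors_granges(anchors, "b")
  hit_a <- GenomicRanges::countOverlaps(ga, drv_gr) > 0
  hit_b <- GenomicRanges::countOverlaps(gb, drv_gr) > 0
  partners <- c(gb[hit_a & !hit_b], ga[hit_b & !hit_a])
  region_set(as.character(GenomeInfoDb::seqnames(partners)),
             GenomicRanges::start(partners), GenomicRanges::end(partners),
             strategy = "enhancer", driver_id = driver_region$driver_id)
}

.bind_anchor_sets <- function(x) {
  if (inherits(x, "LoopAnchorSet")) return(x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "LoopAnchorSet")))
  df <- do.call(rbind, lapply(x, `[[`, "pairs"))
  out <- list(pairs = df)
  class(out) <- "LoopAnchorSet"
  out
}

#' SNPs falling in a region set
#'
#' Positions are compared with the 1-based inclusive intervals: a SNP at an
#' interval start or end is included.
#'
#' @param snp_table data.frame with `id`, `chrom`, `pos`.
#' @param rs a [region_set()].
#' @return character vector of SNP ids, ordered by (chrom, pos).
#' @export
snps_in_regions <- function(snp_table, rs) {
  if (!nrow(rs$intervals)) return(character())
  snp_gr <- GenomicRanges::GRanges(snp_table$chrom,
                                   IRanges::IRanges(snp_table$pos,
                                                    snp_table$pos))
  ## disjoint chromosome sets between SNPs and regions are expected
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(snp_gr, .rs_granges(rs))) > 0
  sel <- snp_table[hits, , drop = FALSE]
  sel <- sel[order(sel$chrom, sel$pos), , drop = FALSE]
  sel$id
}

#' Loop-anchor enrichment around a SNP
#'
#' Tests whether more loop anchors fall within `window` bp of a SNP than
#' expected for a randomly placed region of the same size. The null is built
#' by dropping `n_permutations` equal-size windows uniformly on the supplied
#' chromosome lengths (minus an optional gap mask) and counting overlapping
#' anchors. The permutation-inclusive estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_permutations) avoids p = 0.
#'
#' @param snp_position list/vector with `chrom` and `pos`, e.g.
#'   `c(chrom = "chr21", pos = 42e6)` (pos coerced to numeric).
#' @param anchor_sets a [loop_anchor_set()] or list of them; the test is run
#'   per (cell_line, target) stratum.
#' @param chrom_lengths named numeric vector of chromosome lengths defining
#'   the sampling space for null windows.
#' @param window half-width in bp (default 1 Mbp).
#' @param n_permutations number of null windows (default 100,000).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with `cell_line`, `target`, `observed`,
#'   `expected` (mean null count) and `p`.
#' @export
anchor_enrichment <- function(snp_position, anchor_sets, chrom_lengths,
                              window = 1e6, n_permutations = 1e5,
                              seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  anchors <- .bind_anchor_sets(anchor_sets)
  chrom <- as.character(snp_position[["chrom"]])
  pos <- as.numeric(snp_position[["pos"]])
  p <- anchors$pairs
  ## flatten both anchors of every pair into one interval pool
  flat <- data.frame(
    chrom = c(p$chrom_a, p$chrom_b),
    start = c(p$start_a, p$start_b), end = c(p$end_a, p$end_b),
    cell_line = rep(p$cell_line, 2L), target = rep(p$target, 2L),
    stringsAsFactors = FALSE)
  win_size <- 2 * window + 1
  obs_lo <- pmax(1, pos - window); obs_hi <- pos + window

  set.seed(seed)
  tot <- sum(as.numeric(chrom_lengths))
  u <- runif(n_permutations) * tot
  cum <- cumsum(as.numeric(chrom_lengths))
  idx <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
  null_chrom <- names(chrom_lengths)[idx]
  offset <- u - c(0, cum)[idx]
  null_lo <- pmax(1, offset - window)
  null_hi <- pmin(as.numeric(chrom_lengths)[idx], offset + window)

  strata <- unique(flat[, c("cell_line", "target")])
  out <- lapply(seq_len(nrow(strata)), function(i) {
    sub <- flat[flat$cell_line == strata$cell_line[i] &
                flat$target == strata$target[i], , drop = FALSE]
    observed <- sum(sub$chrom == chrom & sub$start <= obs_hi &
                    sub$end >= obs_lo)
    ## null counts per permutation window, vectorized per chromosome
    null_counts <- numeric(n_permutations)
    for (ch in unique(sub$chrom)) {
      s <- sub[sub$chrom == ch, , drop = FALSE]
      on_ch <- which(null_chrom == ch)
      if (!length(on_ch)) next
      ## count anchors intersecting [lo, hi] via sorted boundary counts
      starts <- sort(s$start); ends <- sort(s$end)
      n_anch <- nrow(s)
      ## anchors NOT overlapping: end < lo or start > hi
      below <- findInterval(null_lo[on_ch] - 1, ends)
      above <- n_anch - findInterval(null_hi[on_ch], starts)
      null_counts[on_ch] <- n_anch - below - above
    }
    data.frame(cell_line = strata$cell_line[i], target = strata$target[i],
               observed = observed, expected = mean(null_counts),
               p = (1 + sum(null_counts >= observed)) / (1 + n_permutations),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
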