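## Readers/writers for the standard formats touched by the pipeline.
## Internal coordinate convention is 1-based inclusive (VCF-style); BED and
## BEDPE are 0-based half-open on disk and converted exactly once, here.

#' Read a VCF of diploid biallelic SNP genotypes into a dosage matrix
#'
#' Parses the GT field into additive alt-allele dosages \{0, 1, 2\} with
#' `./.` mapped to `NA`. Multiallelic records are rejected by default
#' because the association scans assume biallelic SNPs.
#'
#' @param path path to an (uncompressed or bgzipped) VCFv4.2 file.
#' @param multiallelic one of `"error"` (default), `"drop"` or `"split"`.
#'   `"split"` emits one pseudo-SNP per alternate allele, with dosage
#'   counting that allele.
#' @return a list with `dosage` (patients x SNPs integer matrix) and
#'   `snp_table` (data.frame: `id`, `chrom`, `pos`, `ref`, `alt`, `maf`).
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt > 1L
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sprintf("%d multiallelic record(s) (first: %s); use multiallelic = 'drop' or 'split'",
                   sum(multi), names(rr)[which(multi)[1L]]), call. = FALSE)
    if (multiallelic == "drop") {
      vcf <- vcf[!multi]
      rr <- rr[!multi]
      alt <- alt[!multi]
      n_alt <- n_alt[!multi]
    }
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  ids <- names(rr)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_chr <- vapply(as(alt, "CharacterList"), paste, character(1), collapse = ",")

  parse_gt <- function(g, allele) {
    g <- gsub("|", "/", g, fixed = TRUE)
    parts <- strsplit(g, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (any(p == ".")) return(NA_integer_)
      sum(as.integer(p) == allele)
    }, integer(1))
  }

  rows <- list(); tabs <- list()
  for (i in seq_along(ids)) {
    alleles <- if (multiallelic == "split") seq_len(n_alt[i]) else 1L
    for (a in alleles) {
      d <- parse_gt(gt[i, ], a)
      id <- if (n_alt[i] > 1L) sprintf("%s_alt%d", ids[i], a) else ids[i]
      rows[[length(rows) + 1L]] <- d
      tabs[[length(tabs) + 1L]] <- data.frame(
        id = id, chrom = chrom[i], pos = pos[i], ref = ref[i],
        alt = strsplit(alt_chr[i], ",", fixed = TRUE)[[1L]][a],
        stringsAsFactors = FALSE)
    }
  }
  dosage <- t(do.call(rbind, rows))
  snp_table <- do.call(rbind, tabs)
  rownames(dosage) <- colnames(gt)
  colnames(dosage) <- snp_table$id
  snp_table$maf <- apply(dosage, 2L, .maf_from_dosage)
  rownames(snp_table) <- NULL
  list(dosage = dosage, snp_table = snp_table)
}

#' Write a dosage matrix as a VCFv4.2 file
#'
#' Dosages 0/1/2 become GT `0/0`, `0/1`, `1/1`; `NA` becomes `./.`.
#' Heterozygous phase is not represented (unphased output).
#'
#' @param dosage patients x SNPs matrix in \{0, 1, 2, NA\}.
#' @param snp_table data.frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosage, snp_table, path) {
  stopifnot(ncol(dosage) == nrow(snp_table))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=dqtltools",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(snp_table)), function(i) {
    d <- dosage[, i]
    g <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c(snp_table$chrom[i], snp_table$pos[i], snp_table$id[i],
            snp_table$ref[i], snp_table$alt[i], ".", "PASS", ".", "GT", g),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a BED file into a RegionSet
#'
#' BED is 0-based half-open on disk; intervals are converted to the internal
#' 1-based inclusive convention (`start + 1`, `end`).
#'
#' @param path BED file (>= 3 columns; column 4 used as `driver_id` when
#'   present).
#' @param strategy provenance label attached to the returned set.
#' @param merge merge overlapping intervals (default `TRUE`, the RegionSet
#'   invariant). Set `FALSE` to keep one region per BED line.
#' @return a [region_set()] (or a named list of them when the BED carries
#'   multiple names and `merge = FALSE` is not required).
#' @export
read_bed <- function(path, strategy = "linear", merge = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   name = if (!is.null(gr$name)) gr$name else NA_character_,
                   stringsAsFactors = FALSE)
  if (any(df$end < df$start))
    stop("BED interval with end < start", call. = FALSE)
  region_set(df$chrom, df$start, df$end, strategy = strategy,
             driver_id = if (all(is.na(df$name))) NA_character_ else df$name,
             merge = merge)
}

#' Write a RegionSet as BED (0-based half-open)
#'
#' @param rs a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  iv <- rs$intervals
  lines <- sprintf("%s\t%d\t%d\t%s", iv$chrom, iv$start - 1L, iv$end,
                   rs$driver_id %||% ".")
  writeLines(lines, path)
  invisible(path)
}

#' Read chromatin loop anchors from a BEDPE file
#'
#' Expects the standard six BEDPE coordinate columns followed by two label
#' columns, `cell_line` and `target`. Coordinates are converted from
#' 0-based half-open to 1-based inclusive.
#'
#' @param path BEDPE file (no header).
#' @return a [loop_anchor_set()].
#' @export
read_bedpe <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 8L)
    stop("BEDPE must have 6 coordinate columns + cell_line + target",
         call. = FALSE)
  names(df)[1:8] <- c("chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                      "end_b", "cell_line", "target")
  bad <- df$end_a < df$start_a | df$end_b < df$start_b
  if (any(bad))
    stop(sprintf("BEDPE interval with end < start at line %d", which(bad)[1L]),
         call. = FALSE)
  loop_anchor_set(chrom_a = df$chrom_a, start_a = df$start_a + 1L,
                  end_a = df$end_a, chrom_b = df$chrom_b,
                  start_b = df$start_b + 1L, end_b = df$end_b,
                  cell_line = df$cell_line, target = df$target)
}

#' Write a LoopAnchorSet as BEDPE
#' @param anchors a [loop_anchor_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(anchors, path) {
  p <- anchors$pairs
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s\t%s",
                   p$chrom_a, p$start_a - 1L, p$end_a,
                   p$chrom_b, p$start_b - 1L, p$end_b,
                   p$cell_line, p$target)
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a TSV matrix with a header row of column ids
#'
#' @param path TSV path; first column holds row ids.
#' @return numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_tsv_matrix
#' @param m matrix to write.
#' @param id_name header label for the row-id column.
#' @export
write_tsv_matrix <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
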