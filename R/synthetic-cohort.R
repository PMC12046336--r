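## Synthetic multi-cohort generator with the statistical structure the dQTL
## analysis assumes: block-structured LD, drivers generated from a logistic
## model with covariate effects and planted per-allele log-odds, and
## ancestry-shifted allele-frequency panels. Everything is a deterministic
## function of the config seed.

#' Simulation configuration
#'
#' Collects all generative parameters with defaults matching the conditions
#' of the motivating study design: a 427-patient discovery cohort, 17
#' somatic drivers with marginal frequencies spanning 5.1%-57.3%, haplotype
#' blocks with a median of about 7 SNPs, and covariates (5 genetic PCs,
#' age, CNA and SNV mutation burden, clinical ISUP grade group / T category
#' / PSA).
#'
#' @param n_patients cohort size (default 427).
#' @param n_snps approximate number of SNPs before MAF filtering.
#' @param block_length_sampler function(n) returning n block lengths in
#'   SNPs (default 1 + Poisson(6): median about 7).
#' @param maf_range attainable minor-allele-frequency range; SNPs whose
#'   realized MAF falls below the lower bound are dropped.
#' @param ld_decay per-SNP allele-flip probability when copying a haplotype
#'   from the block's ancestral pool; 0 gives perfect within-block LD.
#' @param n_ancestral_haplotypes ancestral pool size per block (default 3,
#'   which guarantees |D'| = 1 within blocks at `ld_decay = 0`).
#' @param n_drivers number of somatic drivers (default 17).
#' @param driver_freqs target marginal driver frequencies (default evenly
#'   spanning 0.051-0.573).
#' @param planted_effects data.frame with columns `snp_id`, `driver_id`,
#'   `per_allele_log_odds` and optional `confounded_by` (a covariate name);
#'   `NULL` for a null cohort.
#' @param covariate_model list of covariate-generation and driver-model
#'   parameters; see Details in the package vignette. `driver_covariates`
#'   holds the log-odds coefficients of (z-scored) age, PC1 and the
#'   type-matched mutation burden in the driver-generating model.
#' @param ancestry_panels list with `populations` (named vector of panel
#'   sizes) and `fst` (Balding-Nichols differentiation per population,
#'   recycled).
#' @param missing_rate genotype missingness rate (default 0).
#' @param seed integer seed; fixes every emitted byte.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_patients = 427L,
                              n_snps = 500L,
                              block_length_sampler = function(n)
                                1L + rpois(n, 6),
                              maf_range = c(0.01, 0.5),
                              ld_decay = 0.005,
                              n_ancestral_haplotypes = 3L,
                              n_drivers = 17L,
                              driver_freqs = NULL,
                              planted_effects = NULL,
                              covariate_model = list(),
                              ancestry_panels = list(
                                populations = c(european = 7718,
                                                african = 4359,
                                                east_asian = 780),
                                fst = c(0.0, 0.12, 0.11)),
                              missing_rate = 0,
                              seed = 1L) {
  if (n_snps < 1L) stop("n_snps must be >= 1", call. = FALSE)
  if (is.null(driver_freqs))
    driver_freqs <- seq(0.051, 0.573, length.out = n_drivers)
  .assert_prob(driver_freqs, "driver_freqs")
  .assert_prob(maf_range, "maf_range", open = FALSE)
  stopifnot(ld_decay >= 0, ld_decay <= 1, length(driver_freqs) == n_drivers)
  cm <- modifyList(list(
    age_mean = 65, age_sd = 7,
    pga_shape1 = 1.5, pga_shape2 = 18,
    snv_density_meanlog = log(0.4), snv_density_sdlog = 0.5,
    psa_meanlog = log(7.5), psa_sdlog = 0.6,
    isup_probs = c(0.25, 0.35, 0.20, 0.12, 0.08),
    t3_prob = 0.4,
    driver_covariates = c(age = 0.2, PC1 = 0.2, burden = 0.3),
    confounder_shift = 0.5), covariate_model)
  out <- list(n_patients = as.integer(n_patients),
              n_snps = as.integer(n_snps),
              block_length_sampler = block_length_sampler,
              maf_range = maf_range, ld_decay = ld_decay,
              n_ancestral_haplotypes = as.integer(n_ancestral_haplotypes),
              n_drivers = as.integer(n_drivers),
              driver_freqs = driver_freqs,
              planted_effects = planted_effects,
              covariate_model = cm,
              ancestry_panels = ancestry_panels,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(out) <- "SimulationConfig"
  out
}

#' Simulate block-structured genotypes
#'
#' Blocks are laid consecutively on "chr1" (SNPs 1 kbp apart, 200 kbp
#' between blocks). Each block has an ancestral haplotype pool; individual
#' haplotypes copy a random pool member with per-SNP flip rate `ld_decay`
#' and diploids are formed by pairing consecutive haplotypes. SNPs that end
#' up monomorphic or below `maf_range[1]` are dropped.
#'
#' @param config a [simulation_config()].
#' @return list with `dosage` (patients x SNPs), `snp_table` (`id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf`, `block_id` ground truth).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "genotypes"))
  n <- config$n_patients
  K <- config$n_ancestral_haplotypes
  ## draw block lengths until n_snps covered
  lens <- integer(0)
  while (sum(lens) < config$n_snps)
    lens <- c(lens, config$block_length_sampler(16L))
  lens <- lens[cumsum(lens) - lens < config$n_snps]
  hap <- matrix(0L, 2L * n, 0L)
  block_id <- integer(0)
  pos <- integer(0)
  cur <- 1L
  ## proper subsets of the ancestral pool (alt-allele carrier sets)
  subsets <- Filter(function(s) length(s) >= 1L && length(s) < K,
                    unlist(lapply(seq_len(K), function(k)
                      utils::combn(K, k, simplify = FALSE)),
                      recursive = FALSE))
  for (b in seq_along(lens)) {
    L <- lens[b]
    ## ancestral pool: K haplotypes with Dirichlet weights; each SNP's alt
    ## allele is carried by a proper subset of the pool chosen so the pool
    ## frequency tracks a target drawn from maf_range. With at most K
    ## haplotype classes per block, K <= 3 implies |D'| = 1 for all
    ## within-block pairs when ld_decay = 0 (at most 3 of 4 gametes).
    ## Weights are redrawn (up to 40 times) until some subset frequency
    ## folds into maf_range, so narrow ranges stay attainable.
    for (attempt in 1:40) {
      w <- stats::rexp(K); w <- w / sum(w)
      folded <- vapply(subsets, function(s)
        min(sum(w[s]), 1 - sum(w[s])), numeric(1))
      in_range <- folded >= config$maf_range[1] &
        folded <= config$maf_range[2]
      if (any(in_range)) break
    }
    anc <- matrix(0L, K, L)
    for (s in seq_len(L)) {
      target <- runif(1, config$maf_range[1], config$maf_range[2])
      cand <- if (any(in_range)) which(in_range) else seq_along(subsets)
      pickset <- cand[sample.int(length(cand), 1L,
                                 prob = 1 / (abs(folded[cand] - target) +
                                             0.02))]
      anc[subsets[[pickset]], s] <- 1L
    }
    pick <- sample.int(K, 2L * n, replace = TRUE, prob = w)
    hb <- anc[pick, , drop = FALSE]
    if (config$ld_decay > 0) {
      flip <- matrix(rbinom(2L * n * L, 1L, config$ld_decay), 2L * n, L)
      hb <- (hb + flip) %% 2L
    }
    hap <- cbind(hap, hb)
    block_id <- c(block_id, rep(b, L))
    pos <- c(pos, cur + seq_len(L) * 1000L)
    cur <- cur + L * 1000L + 200000L
  }
  dosage <- hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(dosage)) < config$missing_rate,
                   nrow(dosage), ncol(dosage))
    dosage[miss] <- NA_integer_
  }
  maf <- apply(dosage, 2L, .maf_from_dosage)
  keep <- !is.na(maf) & maf >= config$maf_range[1] & maf > 0
  if (!any(keep))
    stop("no SNP attained a MAF inside maf_range; widen the range or ",
         "increase n_patients", call. = FALSE)
  dosage <- dosage[, keep, drop = FALSE]
  snp_table <- data.frame(
    id = sprintf("snp%04d", seq_len(sum(keep))),
    chrom = "chr1", pos = pos[keep], ref = "A", alt = "G",
    maf = maf[keep], block_id = block_id[keep], stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("P%04d", seq_len(n))
  colnames(dosage) <- snp_table$id
  list(dosage = dosage, snp_table = snp_table)
}

## covariate table: 5 genetic PCs, age, burdens, clinical features
.simulate_covariates <- function(config, patient_ids) {
  cm <- config$covariate_model
  n <- length(patient_ids)
  cov <- data.frame(
    PC1 = rnorm(n), PC2 = rnorm(n), PC3 = rnorm(n), PC4 = rnorm(n),
    PC5 = rnorm(n),
    age = rnorm(n, cm$age_mean, cm$age_sd),
    pga = stats::rbeta(n, cm$pga_shape1, cm$pga_shape2),
    snv_density = stats::rlnorm(n, cm$snv_density_meanlog,
                                cm$snv_density_sdlog),
    ISUP_GG = sample(1:5, n, replace = TRUE, prob = cm$isup_probs),
    T_category = ifelse(runif(n) < cm$t3_prob, "T3", "T2"),
    PSA = stats::rlnorm(n, cm$psa_meanlog, cm$psa_sdlog),
    stringsAsFactors = FALSE)
  rownames(cov) <- patient_ids
  cov
}

## driver metadata mirroring the driver-type mix of the motivating design:
## 11 CNA losses (7 trunk / 4 branch), 3 CNA gains (2 trunk / 1 branch),
## 1 fusion, 2 SNVs -- recycled for other n_drivers
.driver_metadata <- function(config, snp_table) {
  base <- data.frame(
    type = c(rep("cna_loss", 11), rep("cna_gain", 3), "fusion", "snv",
             "snv"),
    timing = c(rep("trunk", 7), rep("branch", 4), "trunk", "trunk",
               "branch", "trunk", NA, NA), stringsAsFactors = FALSE)
  idx <- ((seq_len(config$n_drivers) - 1L) %% nrow(base)) + 1L
  meta <- base[idx, , drop = FALSE]
  meta$id <- sprintf("driver%02d", seq_len(config$n_drivers))
  meta$frequency <- config$driver_freqs
  ## driver regions: centered on evenly spaced SNP blocks (36 kbp wide)
  blocks <- unique(snp_table$block_id)
  anchor_blocks <- blocks[round(seq(1, length(blocks),
                                    length.out = config$n_drivers))]
  reg <- t(vapply(anchor_blocks, function(b) {
    p <- snp_table$pos[snp_table$block_id == b]
    mid <- round(mean(range(p)))
    c(mid - 18000, mid + 18000)
  }, numeric(2)))
  meta$chrom <- "chr1"
  meta$start <- as.integer(reg[, 1]); meta$end <- as.integer(reg[, 2])
  rownames(meta) <- NULL
  meta[, c("id", "type", "timing", "frequency", "chrom", "start", "end")]
}

## bisection for the intercept that hits the target marginal frequency
.solve_intercept <- function(eta, target, tol = 1e-10, driver_id = "?") {
  f <- function(b0) mean(plogis(b0 + eta)) - target
  lo <- -25; hi <- 25
  if (f(lo) > 0 || f(hi) < 0)
    stop(sprintf("target frequency %.3f unreachable for driver %s",
                 target, driver_id), call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Simulate somatic driver calls from a logistic model
#'
#' P(driver = 1) = logistic(b0 + sum of planted per-allele effects x dosage
#' + covariate terms), with the intercept solved by bisection so the
#' expected marginal frequency matches the configured target to within
#' +/- 0.5%. The burden covariate is matched to driver type (PGA for
#' CNA/fusion drivers, SNV density for SNV drivers) as in the fitted model.
#' Planted effects with `confounded_by` set shift that covariate by
#' genotype first, creating genuine confounding.
#'
#' @param geno result of [simulate_genotypes()].
#' @param covariates covariate data.frame (see `.simulate_covariates`).
#' @param config a [simulation_config()]; `config$planted_effects` holds
#'   the ground-truth effects.
#' @return list with `drivers` (patients x drivers 0/1 matrix),
#'   `driver_meta`, possibly modified `covariates`, and `intercepts`.
#' @export
simulate_drivers <- function(geno, covariates, config) {
  set.seed(derive_seed(config$seed, "drivers"))
  meta <- .driver_metadata(config, geno$snp_table)
  pe <- config$planted_effects
  if (!is.null(pe)) {
    bad_snp <- setdiff(pe$snp_id, colnames(geno$dosage))
    bad_drv <- setdiff(pe$driver_id, meta$id)
    if (length(bad_snp) || length(bad_drv))
      stop("planted effect references unknown snp/driver: ",
           paste(c(bad_snp, bad_drv), collapse = ", "), call. = FALSE)
    ## genotype-dependent covariate shifts (confounding)
    if (!is.null(pe$confounded_by)) {
      cs <- config$covariate_model$confounder_shift
      for (k in which(!is.na(pe$confounded_by) & pe$confounded_by != "")) {
        cv <- pe$confounded_by[k]
        d <- geno$dosage[, pe$snp_id[k]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        covariates[[cv]] <- covariates[[cv]] +
          cs * sd(covariates[[cv]]) * scale(d)[, 1L]
      }
    }
  }
  cc <- config$covariate_model$driver_covariates
  n <- nrow(geno$dosage)
  drivers <- matrix(0L, n, nrow(meta),
                    dimnames = list(rownames(geno$dosage), meta$id))
  intercepts <- numeric(nrow(meta))
  for (j in seq_len(nrow(meta))) {
    burden <- if (meta$type[j] == "snv") covariates$snv_density
              else covariates$pga
    eta <- cc[["age"]] * scale(covariates$age)[, 1L] +
      cc[["PC1"]] * covariates$PC1 +
      cc[["burden"]] * scale(burden)[, 1L]
    if (!is.null(pe)) {
      for (k in which(pe$driver_id == meta$id[j])) {
        d <- geno$dosage[, pe$snp_id[k]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        eta <- eta + pe$per_allele_log_odds[k] * d
      }
    }
    b0 <- .solve_intercept(eta, meta$frequency[j], driver_id = meta$id[j])
    if (abs(mean(plogis(b0 + eta)) - meta$frequency[j]) > 0.005)
      stop(sprintf("intercept solve failed for driver %s", meta$id[j]),
           call. = FALSE)
    intercepts[j] <- b0
    drivers[, j] <- rbinom(n, 1L, plogis(b0 + eta))
  }
  list(drivers = drivers, driver_meta = meta, covariates = covariates,
       intercepts = intercepts)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running genotypes, covariates and drivers from one
#' config. A replication cohort is an independent draw from the same
#' generative parameters under a different seed (optionally dropping CNA
#' timing, mirroring replication data without whole-genome sequencing).
#'
#' @param config a [simulation_config()].
#' @param drop_timing set driver `timing` to `NA` (replication cohorts
#'   without evolutionary timing).
#' @return object of class `Cohort`: `dosage`, `snp_table`, `drivers`,
#'   `driver_meta`, `covariates`.
#' @export
simulate_cohort <- function(config, drop_timing = FALSE) {
  geno <- simulate_genotypes(config)
  set.seed(derive_seed(config$seed, "covariates"))
  covs <- .simulate_covariates(config, rownames(geno$dosage))
  drv <- simulate_drivers(geno, covs, config)
  if (drop_timing) drv$driver_meta$timing <- NA_character_
  out <- list(dosage = geno$dosage, snp_table = geno$snp_table,
              drivers = drv$drivers, driver_meta = drv$driver_meta,
              covariates = drv$covariates)
  class(out) <- "Cohort"
  out
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d SNPs, %d drivers\n",
              nrow(x$dosage), ncol(x$dosage), ncol(x$drivers)))
  invisible(x)
}

#' Simulate chromatin loop anchors
#'
#' Produces background anchor pairs plus planted loops connecting driver
#' regions to distal windows containing chosen SNPs, replicated across a
#' configurable number of cell lines (the multi-cell-line support rule of
#' the spatial strategy keys on this).
#'
#' @param config a [simulation_config()].
#' @param snp_table SNP table (for planting loops onto SNP windows).
#' @param driver_regions data.frame `id`, `chrom`, `start`, `end` (e.g.
#'   `cohort$driver_meta`).
#' @param planted_loops data.frame with `driver_id`, `snp_id`,
#'   `n_cell_lines`, `target`; `NULL` plants none.
#' @param fraction when `planted_loops` is `NULL`, the fraction of drivers
#'   given a random 2-cell-line distal loop (default 0).
#' @param n_background random background anchor pairs per (cell line,
#'   target).
#' @param cell_lines,targets label pools.
#' @param anchor_width width of generated anchors in bp.
#' @param genome_length background sampling space on chr1.
#' @param seed integer seed.
#' @return a [loop_anchor_set()].
#' @export
simulate_loop_anchors <- function(config, snp_table, driver_regions,
                                  planted_loops = NULL, fraction = 0,
                                  n_background = 50L,
                                  cell_lines = c("LNCaP", "DU145", "VCaP",
                                                 "RWPE-1"),
                                  targets = "RNAPII",
                                  anchor_width = 5000L,
                                  genome_length = NULL, seed = NULL) {
  set.seed(derive_seed(seed %||% config$seed, "anchors"))
  if (is.null(genome_length)) genome_length <- max(snp_table$pos) + 1e6
  rows <- list()
  add <- function(c1, s1, e1, c2, s2, e2, cl, tg)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom_a = c1, start_a = as.integer(s1), end_a = as.integer(e1),
      chrom_b = c2, start_b = as.integer(s2), end_b = as.integer(e2),
      cell_line = cl, target = tg, stringsAsFactors = FALSE)
  ## background loops
  for (cl in cell_lines) for (tg in targets) {
    if (n_background < 1L) next
    s1 <- sample.int(genome_length - anchor_width, n_background)
    s2 <- sample.int(genome_length - anchor_width, n_background)
    add("chr1", s1, s1 + anchor_width - 1L, "chr1", s2,
        s2 + anchor_width - 1L, cl, tg)
  }
  if (is.null(planted_loops) && fraction > 0) {
    pick <- which(runif(nrow(driver_regions)) < fraction)
    planted_loops <- do.call(rbind, lapply(pick, function(i) {
      far <- snp_table[abs(snp_table$pos -
                           (driver_regions$start[i] +
                            driver_regions$end[i]) / 2) > 6e5, ,
                       drop = FALSE]
      if (!nrow(far)) return(NULL)
      data.frame(driver_id = driver_regions$id[i],
                 snp_id = far$id[sample.int(nrow(far), 1L)],
                 n_cell_lines = 2L, target = targets[1L],
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(planted_loops) && nrow(planted_loops)) {
    for (k in seq_len(nrow(planted_loops))) {
      i <- match(planted_loops$driver_id[k], driver_regions$id)
      s <- match(planted_loops$snp_id[k], snp_table$id)
      if (is.na(i) || is.na(s))
        stop("planted loop references unknown driver/snp", call. = FALSE)
      a1 <- round((driver_regions$start[i] + driver_regions$end[i]) / 2)
      b1 <- snp_table$pos[s] - round(anchor_width / 2)
      for (cl in cell_lines[seq_len(planted_loops$n_cell_lines[k])])
        add(driver_regions$chrom[i], a1, a1 + anchor_width - 1L,
            snp_table$chrom[s], max(1, b1), max(1, b1) + anchor_width - 1L,
            cl, planted_loops$target[k])
    }
  }
  df <- do.call(rbind, rows)
  loop_anchor_set(df$chrom_a, df$start_a, df$end_a, df$chrom_b, df$start_b,
                  df$end_b, df$cell_line, df$target)
}

#' Simulate molecular trait matrices (methylation / expression / protein)
#'
#' trait = alpha + beta x dosage (planted QTLs) + small age and PC1 effects
#' + Gaussian noise. A paired reference (normal-tissue) matrix is generated
#' with the same structure; planted QTLs flagged `tumor_specific` have
#' beta = 0 in the reference matrix.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param planted_qtls data.frame `snp_id`, `trait_id`, `beta`, optional
#'   logical `tumor_specific`; `NULL` for a null trait set.
#' @param n_traits number of traits.
#' @param sigma residual standard deviation (default 1).
#' @param seed integer seed (defaults to a derivation from the cohort's
#'   dimensions; pass explicitly for full control).
#' @return list with `tumor` and `reference` (traits x patients matrices),
#'   `trait_meta` (`trait_id`, `chrom`, `pos`).
#' @export
simulate_molecular_traits <- function(cohort, planted_qtls = NULL,
                                      n_traits = 50L, sigma = 1,
                                      seed = 1L) {
  set.seed(derive_seed(seed, "traits"))
  n <- nrow(cohort$dosage)
  ids <- sprintf("trait%03d", seq_len(n_traits))
  ## traits placed near a random SNP so +/- 500 kbp windows are non-trivial
  anchor <- sample.int(nrow(cohort$snp_table), n_traits, replace = TRUE)
  pos <- cohort$snp_table$pos[anchor] + sample(-4e5:4e5, n_traits,
                                               replace = TRUE)
  meta <- data.frame(trait_id = ids, chrom = "chr1", pos = pmax(1, pos),
                     stringsAsFactors = FALSE)
  base_cov <- 0.1 * scale(cohort$covariates$age)[, 1L] +
    0.1 * cohort$covariates$PC1
  make <- function(tumor) {
    m <- matrix(rnorm(n_traits * n, 0, sigma), n_traits, n,
                dimnames = list(ids, rownames(cohort$dosage)))
    m <- m + matrix(base_cov, n_traits, n, byrow = TRUE)
    if (!is.null(planted_qtls)) {
      for (k in seq_len(nrow(planted_qtls))) {
        ts <- isTRUE(planted_qtls$tumor_specific[k])
        if (!tumor && ts) next
        ti <- match(planted_qtls$trait_id[k], ids)
        d <- cohort$dosage[, planted_qtls$snp_id[k]]
        d[is.na(d)] <- mean(d, na.rm = TRUE)
        m[ti, ] <- m[ti, ] + planted_qtls$beta[k] * d
      }
      ## planted traits sit right next to their SNP
      ti <- match(planted_qtls$trait_id, ids)
      si <- match(planted_qtls$snp_id, cohort$snp_table$id)
      meta$pos[ti] <<- cohort$snp_table$pos[si] + 1000L
    }
    m
  }
  tumor <- make(TRUE)
  reference <- make(FALSE)
  list(tumor = tumor, reference = reference, trait_meta = meta)
}

#' Simulate ancestry-stratified population allele frequencies
#'
#' Per population, alt-allele frequencies are drawn from a Balding-Nichols
#' Beta distribution around the cohort frequency with the configured Fst
#' (Fst = 0 reproduces the cohort frequency exactly). Output matches the
#' population-frequency TSV schema consumed by [vaf_ancestry_test()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config the [simulation_config()] holding `ancestry_panels`.
#' @param snp_ids SNPs to report (default all).
#' @return data.frame `snp`, `population`, `vaf`, `n_individuals`.
#' @export
simulate_ancestry_freqs <- function(cohort, config, snp_ids = NULL) {
  set.seed(derive_seed(config$seed, "ancestry"))
  snp_ids <- snp_ids %||% cohort$snp_table$id
  pops <- config$ancestry_panels$populations
  fst <- rep_len(config$ancestry_panels$fst, length(pops))
  base <- vapply(snp_ids, function(s)
    .aaf_from_dosage(cohort$dosage[, s]), numeric(1))
  out <- list()
  for (k in seq_along(pops)) {
    p <- if (fst[k] <= 0) base else {
      a <- base * (1 - fst[k]) / fst[k]
      b <- (1 - base) * (1 - fst[k]) / fst[k]
      stats::rbeta(length(base), a, b)
    }
    out[[k]] <- data.frame(snp = snp_ids, population = names(pops)[k],
                           vaf = p, n_individuals = unname(pops[k]),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Export a cohort to standard files
#'
#' Writes `genotypes.vcf` (VCFv4.2), `drivers.tsv`, `covariates.tsv`,
#' `driver_regions.bed` (0-based half-open) and, when given,
#' `anchors.bedpe` and trait matrices. Reading the files back reproduces
#' the in-memory matrices exactly.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param anchors optional [loop_anchor_set()].
#' @param traits optional [simulate_molecular_traits()] result.
#' @return named vector of written paths, invisibly.
#' @export
export_cohort <- function(cohort, dir, anchors = NULL, traits = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             drivers = file.path(dir, "drivers.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             bed = file.path(dir, "driver_regions.bed"))
  write_vcf(cohort$dosage, cohort$snp_table, paths["vcf"])
  drv <- data.frame(patient = rownames(cohort$drivers), cohort$drivers,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(drv, paths["drivers"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  cov <- data.frame(patient = rownames(cohort$covariates),
                    cohort$covariates, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(cov, paths["covariates"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  m <- cohort$driver_meta
  writeLines(sprintf("%s\t%d\t%d\t%s", m$chrom, m$start - 1L, m$end, m$id),
             paths["bed"])
  if (!is.null(anchors)) {
    paths["bedpe"] <- file.path(dir, "anchors.bedpe")
    write_bedpe(anchors, paths["bedpe"])
  }
  if (!is.null(traits)) {
    paths["traits_tumor"] <- file.path(dir, "traits_tumor.tsv")
    paths["traits_reference"] <- file.path(dir, "traits_reference.tsv")
    write_tsv_matrix(traits$tumor, paths["traits_tumor"], "trait_id")
    write_tsv_matrix(traits$reference, paths["traits_reference"],
                     "trait_id")
  }
  invisible(paths)
}
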