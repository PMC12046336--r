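## Orchestration: one config drives simulate -> regions -> blocks -> scan
## -> tag -> replicate -> meta -> power -> co-occurrence, with deterministic
## per-stage seeding and a machine-readable manifest.

#' Pipeline run configuration
#'
#' @param simulation a [simulation_config()] for the discovery cohort, or
#'   `NULL` when `cohort_paths` is given.
#' @param replication_simulation optional [simulation_config()] for an
#'   independent replication cohort (timing dropped).
#' @param cohort_paths optional named list of file paths (`vcf`,
#'   `drivers`, `covariates`, `bed`) to load instead of simulating.
#' @param strategies subset of `c("risk", "linear", "spatial",
#'   "enhancer")` to run.
#' @param risk_snps risk-SNP ids for the risk strategy (`NULL`: skipped).
#' @param anchors optional [loop_anchor_set()] for spatial/enhancer
#'   strategies (`NULL`: simulated when those strategies are enabled).
#' @param thresholds named list; defaults: `maf` 0.05,
#'   `alpha_bonferroni` 0.1, `q_risk` 0.1, `q_replication` 0.1, `q_meta`
#'   0.1, `q_pairs` 0.05, `min_patients` 15, `flank` 5e5, `anchor_window`
#'   1e6, `min_driver_freq` 0.05.
#' @param seed global seed fanned out to stages via [derive_seed()].
#' @param out_dir output directory for result TSVs and the manifest.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(simulation = simulation_config(),
                       replication_simulation = NULL,
                       cohort_paths = NULL,
                       strategies = c("linear"),
                       risk_snps = NULL, anchors = NULL,
                       thresholds = list(), seed = 1L,
                       out_dir = tempfile("dqtl_run_")) {
  th <- modifyList(list(maf = 0.05, alpha_bonferroni = 0.1, q_risk = 0.1,
                        q_replication = 0.1, q_meta = 0.1, q_pairs = 0.05,
                        min_patients = 15L, flank = 5e5,
                        anchor_window = 1e6, min_driver_freq = 0.05),
                   thresholds)
  for (nm in c("maf", "alpha_bonferroni", "q_risk", "q_replication",
               "q_meta", "q_pairs"))
    if (th[[nm]] <= 0 || th[[nm]] >= 1)
      stop(sprintf("threshold '%s' must lie in (0, 1)", nm), call. = FALSE)
  bad <- setdiff(strategies, c("risk", "linear", "spatial", "enhancer"))
  if (length(bad)) stop("unknown strategies: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- list(simulation = simulation,
              replication_simulation = replication_simulation,
              cohort_paths = cohort_paths, strategies = strategies,
              risk_snps = risk_snps, anchors = anchors, thresholds = th,
              seed = as.integer(seed), out_dir = out_dir)
  class(out) <- "RunConfig"
  out
}

.load_cohort_from_paths <- function(paths) {
  geno <- read_vcf(paths$vcf)
  drv <- read.table(paths$drivers, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  drivers <- as.matrix(drv[, -1L, drop = FALSE])
  rownames(drivers) <- drv[[1L]]
  cov <- read.table(paths$covariates, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(cov) <- cov[[1L]]
  cov <- cov[, -1L, drop = FALSE]
  bed <- read.table(paths$bed, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  meta <- data.frame(id = bed[[4L]], type = "cna_loss",
                     timing = NA_character_, frequency = NA_real_,
                     chrom = bed[[1L]], start = bed[[2L]] + 1L,
                     end = bed[[3L]], stringsAsFactors = FALSE)
  out <- list(dosage = geno$dosage, snp_table = geno$snp_table,
              drivers = drivers, driver_meta = meta, covariates = cov)
  class(out) <- "Cohort"
  out
}

#' Run the full dQTL pipeline
#'
#' Executes the enabled stages in dependency order and writes result TSVs
#' plus a JSON manifest (seeds, per-stage row counts, thresholds) to
#' `config$out_dir`. Identical config + seed give byte-identical outputs.
#' A failed stage is recorded in the manifest and dependent stages are
#' skipped.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `cohort`, per-stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  th <- config$thresholds
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, thresholds = th,
                   strategies = config$strategies, stages = list())
  results <- list()
  mark <- function(stage, status, n = NA_integer_)
    manifest$stages[[stage]] <<- list(status = status, rows = n)

  ## cohort
  cohort <- tryCatch({
    if (!is.null(config$cohort_paths))
      .load_cohort_from_paths(config$cohort_paths)
    else {
      sim <- config$simulation
      sim$seed <- derive_seed(config$seed, "cohort")
      simulate_cohort(sim)
    }
  }, error = function(e) e)
  if (inherits(cohort, "error")) {
    mark("cohort", paste("failed:", conditionMessage(cohort)))
    .write_manifest(manifest, config$out_dir)
    return(invisible(list(manifest = manifest)))
  }
  mark("cohort", "ok", nrow(cohort$dosage))
  results$cohort <- cohort
  drivers <- eligible_drivers(cohort, th$min_driver_freq)

  anchors <- config$anchors
  if (is.null(anchors) &&
      any(c("spatial", "enhancer") %in% config$strategies) &&
      !is.null(config$simulation))
    anchors <- simulate_loop_anchors(
      config$simulation, cohort$snp_table, cohort$driver_meta,
      fraction = 0.5, seed = derive_seed(config$seed, "loops"))

  ## discovery scans
  scans <- list(); tags <- list()
  if ("risk" %in% config$strategies && !is.null(config$risk_snps)) {
    r <- scan_risk(cohort, config$risk_snps, drivers,
                   q_threshold = th$q_risk)
    scans$risk <- r
    mark("scan_risk", "ok", nrow(r))
  }
  local_strategies <- intersect(config$strategies,
                                c("linear", "spatial", "enhancer"))
  for (strat in local_strategies) {
    rows <- list()
    for (d in drivers) {
      m <- cohort$driver_meta[cohort$driver_meta$id == d, , drop = FALSE]
      drv_rs <- region_set(m$chrom, m$start, m$end, strategy = "linear",
                           driver_id = d)
      rs <- switch(strat,
        linear = linear_window(drv_rs, flank = th$flank),
        spatial = if (is.null(anchors)) NULL else
          spatial_regions(drv_rs, anchors, min_cell_lines = 2,
                          exclude = linear_window(drv_rs,
                                                  flank = th$flank)),
        enhancer = if (is.null(anchors)) NULL else
          enhancer_regions(drv_rs, anchors))
      if (is.null(rs)) next
      sc <- scan_local(cohort, d, strat, rs,
                       alpha = th$alpha_bonferroni, min_maf = th$maf,
                       max_span_snps = 25L)
      if (!nrow(sc$results)) next
      rows[[d]] <- sc$results
      tg <- select_tag_snps(sc$results, sc$block_set)
      if (nrow(tg)) tags[[paste(strat, d)]] <- tg
    }
    scans[[strat]] <- do.call(rbind, rows)
    mark(paste0("scan_", strat), "ok",
         if (is.null(scans[[strat]])) 0L else nrow(scans[[strat]]))
  }
  results$scans <- scans
  results$tags <- if (length(tags)) do.call(rbind, tags) else NULL

  ## replication + meta
  if (!is.null(config$replication_simulation) &&
      !is.null(results$tags) && nrow(results$tags)) {
    rep_sim <- config$replication_simulation
    rep_sim$seed <- derive_seed(config$seed, "replication")
    rep_cohort <- simulate_cohort(rep_sim, drop_timing = TRUE)
    rep <- test_replication(results$tags, rep_cohort,
                            q_threshold = th$q_replication)
    results$replication <- rep
    mark("replication", "ok", nrow(rep))
    conc <- rep[rep$concordant %in% TRUE, , drop = FALSE]
    if (nrow(conc)) {
      est <- rbind(
        data.frame(snp_id = conc$snp_id, driver_id = conc$driver_id,
                   cohort = "discovery", beta = conc$beta_discovery,
                   se = conc$se_discovery, stringsAsFactors = FALSE),
        data.frame(snp_id = conc$snp_id, driver_id = conc$driver_id,
                   cohort = "replication", beta = conc$beta_replication,
                   se = conc$se_replication, stringsAsFactors = FALSE))
      results$meta <- meta_analyze_set(est, q_threshold = th$q_meta)
      mark("meta", "ok", nrow(results$meta))
    }
  }

  ## co-occurrence
  pairs <- pairwise_tests(cohort$drivers, min_patients = th$min_patients,
                          q_threshold = th$q_pairs)
  results$cooccurrence <- pairs
  mark("cooccurrence", "ok", if (is.null(pairs)) 0L else nrow(pairs))

  ## power grid at the cohort size
  pg <- power_grid(maf_grid = c(0.1, 0.25, 0.4),
                   or_grid = c(1.5, 2, 3),
                   freq_grid = c(0.05, 0.2, 0.5),
                   n = nrow(cohort$dosage), alpha = 3.7e-4)
  results$power <- pg
  mark("power", "ok", length(pg$power))

  ## outputs
  for (nm in names(scans))
    if (!is.null(scans[[nm]]))
      write.table(scans[[nm]],
                  file.path(config$out_dir, sprintf("scan_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$tags))
    write.table(results$tags, file.path(config$out_dir, "tag_snps.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$replication))
    write.table(results$replication,
                file.path(config$out_dir, "replication.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$meta))
    write.table(results$meta, file.path(config$out_dir, "meta.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pairs))
    write.table(pairs, file.path(config$out_dir, "cooccurrence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(manifest, config$out_dir)
  results$manifest <- manifest
  invisible(results)
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Validate pipeline input files
#'
#' Parses the given VCF/TSV/BED/BEDPE files, cross-references patient and
#' driver identifiers, and checks coordinate sanity. Returns a
#' machine-readable issue report rather than stopping at the first
#' problem.
#'
#' @param paths named list with any of `vcf`, `drivers`, `covariates`,
#'   `bed`, `bedpe`.
#' @return list with `ok` (logical) and `issues` (data.frame `file`,
#'   `issue`).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  note <- function(file, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, issue = issue, stringsAsFactors = FALSE)
  geno <- NULL
  if (!is.null(paths$vcf)) {
    geno <- tryCatch(read_vcf(paths$vcf), error = function(e) {
      note("vcf", conditionMessage(e)); NULL })
  }
  drv <- NULL
  if (!is.null(paths$drivers)) {
    drv <- tryCatch(read.table(paths$drivers, sep = "\t", header = TRUE,
                               check.names = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) {
                      note("drivers", conditionMessage(e)); NULL })
    if (!is.null(drv) && !is.null(geno)) {
      extra <- setdiff(drv[[1L]], rownames(geno$dosage))
      if (length(extra))
        note("drivers", paste("patients absent from VCF:",
                              paste(extra, collapse = ", ")))
    }
    if (!is.null(drv)) {
      vals <- unlist(drv[, -1L, drop = FALSE])
      if (!all(vals %in% c(0, 1, NA)))
        note("drivers", "non-binary driver calls")
    }
  }
  if (!is.null(paths$covariates) && !is.null(geno)) {
    cov <- tryCatch(read.table(paths$covariates, sep = "\t", header = TRUE,
                               check.names = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) {
                      note("covariates", conditionMessage(e)); NULL })
    if (!is.null(cov)) {
      extra <- setdiff(cov[[1L]], rownames(geno$dosage))
      if (length(extra))
        note("covariates", paste("patients absent from VCF:",
                                 paste(extra, collapse = ", ")))
    }
  }
  if (!is.null(paths$bed)) {
    bed <- tryCatch(read.table(paths$bed, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) {
                      note("bed", conditionMessage(e)); NULL })
    if (!is.null(bed) && any(bed[[3L]] < bed[[2L]]))
      note("bed", "interval with end < start")
  }
  if (!is.null(paths$bedpe))
    tryCatch(read_bedpe(paths$bedpe),
             error = function(e) note("bedpe", conditionMessage(e)))
  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(file = character(), issue = character(),
                            stringsAsFactors = FALSE)
  list(ok = nrow(issues) == 0L, issues = issues)
}

#' Command-line entry point
#'
#' Dispatches the `dqtl` subcommands (`simulate`, `run`, `cooccur`,
#' `power`; the scan/replicate/meta/characterize stages run inside `run`
#' via strategy toggles). Installed as `inst/cli/dqtl`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
dqtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dqtl <simulate|run|cooccur|power> [--seed S] [--out-dir D]",
    "  simulate: [--n-patients N] [--n-snps M]",
    "  run:      [--config config.json]",
    "  cooccur:  --drivers drivers.tsv [--min-patients 15]",
    "  power:    --n N --alpha A", sep = "\n")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  opt <- list(seed = 1L, `out-dir` = ".", `n-patients` = 200L,
              `n-snps` = 100L, `min-patients` = 15L, n = 427, alpha = 0.05,
              config = NULL, drivers = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opt$seed)
  out_dir <- opt$`out-dir`
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "simulate") {
    cfg <- simulation_config(n_patients = as.integer(opt$`n-patients`),
                             n_snps = as.integer(opt$`n-snps`),
                             seed = seed)
    cohort <- simulate_cohort(cfg)
    export_cohort(cohort, out_dir)
    message(sprintf("wrote cohort (%d patients, %d SNPs) to %s",
                    nrow(cohort$dosage), ncol(cohort$dosage), out_dir))
  } else if (cmd == "run") {
    rc <- if (!is.null(opt$config)) {
      j <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
      run_config(simulation = do.call(simulation_config,
                                      j$simulation %||% list()),
                 strategies = j$strategies %||% "linear",
                 thresholds = j$thresholds %||% list(),
                 seed = seed, out_dir = out_dir)
    } else run_config(seed = seed, out_dir = out_dir)
    run_pipeline(rc)
    message("pipeline complete: ", out_dir)
  } else if (cmd == "cooccur") {
    drv <- read.table(opt$drivers, sep = "\t", header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(drv[, -1L, drop = FALSE])
    rownames(m) <- drv[[1L]]
    res <- pairwise_tests(m, min_patients = as.integer(opt$`min-patients`))
    write.table(res, file.path(out_dir, "cooccurrence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message("wrote ", file.path(out_dir, "cooccurrence.tsv"))
  } else if (cmd == "power") {
    pg <- power_grid(c(0.1, 0.25, 0.4), c(1.5, 2, 3), c(0.05, 0.2, 0.5),
                     n = as.numeric(opt$n), alpha = as.numeric(opt$alpha))
    write.table(as.data.frame.table(pg$power, responseName = "power"),
                file.path(out_dir, "power_grid.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    message("wrote ", file.path(out_dir, "power_grid.tsv"))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
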