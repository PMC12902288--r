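# Configuration-driven orchestration: simulate/ingest -> filter -> freqs ->
# D / f_dM / f3 -> windows -> scan, with optional SFS fitting and a
# reproducibility manifest. A single YAML (or list) config is the source
# of truth; reruns with an identical config reproduce identical outputs.

pipeline_defaults <- function() {
  list(
    input = list(preset = "study_pulse", phi = 0.1,
                 vcf = NULL, popmap = NULL,
                 n_loci = 950, locus_length = 300, n_contigs = 19,
                 # diploid sampling mirroring the system's resequencing set
                 sampling = list(HS = 10, TP_E = 9, TP_M = 8, TP_W = 8, J = 5),
                 missing_rate = 0.05),
    filters = list(max_missing = 0.20, min_qual = 30, min_maf = 0.05),
    roles = list(P1 = "TP_W", P2 = "TP_E", P3 = "HS", O = "J"),
    window = list(width = 10000),
    dstat = list(block_size_snps = 1000),
    f3 = list(block_size_snps = 500, C = "TP_E", A = "HS", B = "TP_W"),
    fdm = list(min_sites = 5, quantile = 0.95),
    scan = list(quantile = 0.95, mode = "both",
                group1 = "TP_E", group2 = "HS"),
    sfs = list(enabled = FALSE, pops = c("TP_E", "HS")),
    evidence = list(K = 16),
    seed = 1,
    outdir = "introflow_out")
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects unknown keys, and range-checks thresholds. The
#' configuration may be a YAML file path or a nested list.
#'
#' @param config path to a YAML file, or a list.
#' @return the normalized configuration list (class `pipeline_config`), or
#'   an error listing every violation with its key path.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML file path")
  def <- pipeline_defaults()
  errors <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errors <- c(errors, paste0("unknown key: ", unknown))
  for (k in intersect(names(config), names(def))) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      bad <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(bad)) errors <- c(errors, paste0("unknown key: ", k, ".", bad))
    }
  }
  cfg <- modifyList(def, config)
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(cfg$filters$max_missing >= 0 && cfg$filters$max_missing <= 1,
      "filters.max_missing: must be in [0, 1]")
  chk(cfg$filters$min_maf >= 0 && cfg$filters$min_maf <= 0.5,
      "filters.min_maf: must be in [0, 0.5]")
  chk(cfg$fdm$quantile > 0 && cfg$fdm$quantile < 1,
      "fdm.quantile: must be in (0, 1)")
  chk(cfg$scan$quantile > 0 && cfg$scan$quantile < 1,
      "scan.quantile: must be in (0, 1)")
  chk(cfg$window$width > 0, "window.width: must be positive")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "seed: a single explicit seed is required")
  if (length(errors)) stop(paste(errors, collapse = "; "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order: data acquisition
#' (simulation preset or VCF ingestion), variant filtering, polarized
#' allele frequencies, genome-wide and per-contig Patterson's D, windowed
#' f_dM with outlier calling, f3, windowed diversity statistics and the
#' selection scan, and (optionally) joint-SFS extraction. Per-stage TSV /
#' JSON outputs, a combined JSON report and a reproducibility manifest
#' (config hash, seed, package version) are written under `outdir`.
#'
#' @param config a config accepted by [validate_config()].
#' @return the report list, invisibly; files under `cfg$outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...),
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  report <- list()
  stage <- function(name, expr) {
    logf("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logf("stage %s: done", name)
    out
  }

  gm <- stage("input", {
    if (!is.null(cfg$input$vcf)) {
      read_vcf(cfg$input$vcf, cfg$input$popmap)
    } else {
      model <- scenario_preset(cfg$input$preset, phi = cfg$input$phi)
      sim <- simulate_dataset(model, unlist(cfg$input$sampling),
                              n_loci = cfg$input$n_loci,
                              locus_length = cfg$input$locus_length,
                              seed = cfg$seed,
                              n_contigs = cfg$input$n_contigs)
      if (cfg$input$missing_rate > 0)
        sim <- degrade_dataset(sim, cfg$input$missing_rate,
                               seed = cfg$seed + 1)
      as_genotype_matrix(sim)
    }
  })
  report$n_sites_raw <- nrow(gm$sites)

  gm <- stage("filter", filter_variants(gm, cfg$filters$max_missing,
                                        cfg$filters$min_qual,
                                        cfg$filters$min_maf))
  report$filter_counts <- as.list(attr(gm, "filter_counts"))
  report$n_sites <- nrow(gm$sites)
  logf("sites retained: %d", nrow(gm$sites))

  freqs <- stage("freqs", allele_freqs(gm, unlist(cfg$roles)))
  d <- stage("dstat", patterson_d(freqs, cfg$dstat$block_size_snps))
  report$dstat <- d[c("d", "se", "z", "n_informative_sites", "significant")]
  dchrom <- stage("dstat_chrom", chrom_scan_d(freqs,
                                              block_size_snps = max(50, cfg$dstat$block_size_snps %/% 4)))
  write_tsv(dchrom, file.path(cfg$outdir, "dstat_by_contig.tsv"))

  windows <- make_windows(gm$contigs, cfg$window$width)
  fdm <- stage("fdm", fdm_windows(freqs, windows, cfg$fdm$min_sites))
  out_fdm <- stage("fdm_outliers",
                   if (nrow(fdm)) fdm_outliers(fdm, cfg$fdm$quantile)
                   else list(threshold = NA, outliers = fdm))
  write_tsv(fdm, file.path(cfg$outdir, "fdm_windows.tsv"))
  report$fdm <- list(n_windows = nrow(fdm),
                     mean_fdm = if (nrow(fdm)) mean(fdm$fdm) else NA,
                     threshold = out_fdm$threshold,
                     n_outliers = nrow(out_fdm$outliers))

  f3r <- stage("f3", {
    fr3 <- allele_freqs(gm, c(C = cfg$f3$C, A = cfg$f3$A, B = cfg$f3$B,
                              O = unlist(cfg$roles)[["O"]]))
    f3_stat(fr3, cfg$f3$block_size_snps)
  })
  report$f3 <- f3r[c("f3", "se", "z", "call")]

  wd <- stage("windows", window_diversity(gm, windows = windows))
  write_tsv(wd, file.path(cfg$outdir, "window_stats.tsv"))

  report$scan <- stage("scan", {
    g1 <- cfg$scan$group1; g2 <- cfg$scan$group2
    fst_col <- paste0("fst_", g1, "_", g2)
    if (!fst_col %in% names(wd)) fst_col <- paste0("fst_", g2, "_", g1)
    sc <- selection_scan(wd[[fst_col]], wd[[paste0("pi_", g1)]],
                         wd[[paste0("pi_", g2)]],
                         wd[c("contig", "start", "end")],
                         quantile = cfg$scan$quantile, mode = cfg$scan$mode)
    write_tsv(sc$scores, file.path(cfg$outdir, "selection_scan.tsv"))
    list(n_outliers = nrow(sc$outliers), n_excluded = sc$n_excluded)
  })

  if (isTRUE(cfg$sfs$enabled)) {
    sfs <- stage("sfs", joint_sfs(polarize_by_outgroup(gm, unlist(cfg$roles)[["O"]]),
                                  cfg$sfs$pops))
    write_tsv(as.data.frame(sfs$counts), file.path(cfg$outdir, "joint_sfs.tsv"))
    report$sfs_total <- sfs$total
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("introflow")),
    seed = cfg$seed,
    config = unclass(cfg))
  cfg_file <- file.path(cfg$outdir, "config_normalized.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

write_tsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
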