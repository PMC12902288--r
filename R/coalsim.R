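#' @useDynLib introflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom quantile sd var optim acf dhyper
#'   fisher.test setNames rgamma
#' @importFrom utils write.table read.table modifyList
NULL

# ---------------------------------------------------------------------------
# Demographic models
# ---------------------------------------------------------------------------

#' Construct a demographic model
#'
#' A demographic model is a set of demes (each with a constant diploid
#' effective size), a time-ordered schedule of events looking backwards in
#' time, a per-site per-generation mutation rate and a generation time.
#' Ancestral populations are ordinary demes: a `split` event merges a child
#' deme into its parent (backwards in time), so a model with all splits
#' applied must leave exactly one root deme.
#'
#' Event constructors:
#' * `ev_split(time, child, parent)` — backwards in time, all lineages of
#'   `child` join `parent` at `time` (generations); `child` ceases to exist
#'   further back.
#' * `ev_pulse(time, source, dest, prop)` — an instantaneous admixture pulse
#'   in which, forwards in time, a proportion `prop` (phi) of `dest` is
#'   replaced by migrants from `source`; backwards, each lineage in `dest`
#'   relocates to `source` independently with probability phi.
#' * `ev_migration(time, rates)` — from `time` backwards, the backwards
#'   migration-rate matrix becomes `rates` (entry `[i, j]` = per-generation
#'   probability that a lineage currently in deme i traces back to deme j).
#'
#' Event times must be non-decreasing; simultaneous events are applied in
#' listed order (two splits at the same time express a clean merge of two
#' sisters into a named ancestor).
#'
#' @param demes data.frame with columns `name` and `ne` (diploid effective
#'   size; must be positive).
#' @param events list of events built with [ev_split()], [ev_pulse()],
#'   [ev_migration()].
#' @param mutation_rate per-site per-generation mutation rate.
#' @param generation_time generation time in years (used only when scaling
#'   to absolute units).
#' @return an object of class `demographic_model`.
#' @seealso [scenario_preset()], [simulate_dataset()]
#' @export
demographic_model <- function(demes, events = list(),
                              mutation_rate = 6.675e-8,
                              generation_time = 10) {
  stopifnot(is.data.frame(demes), all(c("name", "ne") %in% names(demes)))
  demes$name <- as.character(demes$name)
  if (anyDuplicated(demes$name)) stop("duplicate deme names")
  if (any(demes$ne <= 0)) stop("all Ne must be > 0")
  if (mutation_rate <= 0) stop("mutation_rate must be > 0")
  if (generation_time <= 0) stop("generation_time must be > 0")

  times <- vapply(events, function(e) e$time, numeric(1))
  if (length(times) && any(diff(times) < 0))
    stop("event times must be non-decreasing (backwards in time)")
  nm <- demes$name
  alive <- setNames(rep(TRUE, length(nm)), nm)
  for (e in events) {
    ref <- switch(e$type, split = c(e$child, e$parent),
                  pulse = c(e$source, e$dest), migration = character(0))
    bad <- setdiff(ref, nm)
    if (length(bad)) stop("event refers to unknown deme: ", bad[1])
    if (e$type == "split") {
      if (!alive[[e$child]]) stop("deme already merged: ", e$child)
      if (!alive[[e$parent]]) stop("split into merged deme: ", e$parent)
      alive[[e$child]] <- FALSE
    }
    if (e$type == "pulse") {
      if (e$prop < 0 || e$prop > 1) stop("pulse proportion phi must be in [0, 1]")
      if (!alive[[e$source]] || !alive[[e$dest]])
        stop("pulse involves a merged deme")
    }
    if (e$type == "migration") {
      if (!is.matrix(e$rates) || any(e$rates < 0))
        stop("migration rates must form a non-negative matrix")
      if (!identical(dim(e$rates), c(length(nm), length(nm))) &&
          !identical(sort(rownames(e$rates)), sort(nm)))
        stop("migration matrix must cover all demes (use deme names)")
    }
  }
  if (sum(alive) != 1)
    stop("exactly one root deme must remain after all splits; still alive: ",
         paste(names(alive)[alive], collapse = ", "))
  structure(list(demes = demes, events = events,
                 mutation_rate = mutation_rate,
                 generation_time = generation_time,
                 root = names(alive)[alive]),
            class = "demographic_model")
}

#' @rdname demographic_model
#' @param time event time in generations before present.
#' @param child,parent deme names for a split.
#' @export
ev_split <- function(time, child, parent)
  list(type = "split", time = time, child = child, parent = parent)

#' @rdname demographic_model
#' @param source,dest deme names for a pulse (forward-time direction
#'   `source -> dest`).
#' @param prop admixture proportion phi in \[0, 1\].
#' @export
ev_pulse <- function(time, source, dest, prop)
  list(type = "pulse", time = time, source = source, dest = dest, prop = prop)

#' @rdname demographic_model
#' @param rates named square matrix of backwards migration rates per
#'   generation.
#' @export
ev_migration <- function(time, rates)
  list(type = "migration", time = time, rates = rates)

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model> ", nrow(x$demes), " demes, root = ", x$root, "\n",
      sep = "")
  cat("  demes:", paste0(x$demes$name, " (Ne=", x$demes$ne, ")",
                         collapse = ", "), "\n")
  for (e in x$events) {
    lab <- switch(e$type,
      split = sprintf("t=%g split %s -> %s", e$time, e$child, e$parent),
      pulse = sprintf("t=%g pulse %s -> %s (phi=%g)", e$time, e$source,
                      e$dest, e$prop),
      migration = sprintf("t=%g migration-rate change", e$time))
    cat("  ", lab, "\n", sep = "")
  }
  cat("  mu =", format(x$mutation_rate), " /site/gen; generation time =",
      x$generation_time, "y\n")
  invisible(x)
}

# empty migration matrix helper
mig_matrix <- function(nm, entries = list()) {
  m <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (e in entries) m[e[[1]], e[[2]]] <- e[[3]]
  m
}

# ---------------------------------------------------------------------------
# Scenario presets
# ---------------------------------------------------------------------------

#' Pre-parameterized demographic scenarios
#'
#' `"study_pulse"` is a five-deme model of the two-species orchid system: a
#' lithophytic donor species (HS), three ecotypes of the recipient species
#' (TP_E, TP_M, TP_W) and an outgroup (J). Split times follow the system's
#' calibration (species split 6.4 Mya; TP_W at 36.93 kya; TP_E/TP_M at
#' 3.56 kya; 10-year generations). A window of weak symmetric migration
#' between HS and the recipient's common ancestor spans 36.93-140 kya
#' (secondary contact during the Last Interglacial), and a single recent
#' unidirectional pulse HS -> TP_E (default phi = 0.1) at 1.8 kya carries
#' the introgression signal. `"study_null"` is identical with phi = 0.
#'
#' The four `pair_IM_*` presets are two-deme isolation-with-migration
#' templates distinguished only by their migration epoch structure over
#' `[0, t_split)` (backwards time): migration in the older half only
#' (`early`), the recent half only (`recent`), throughout (`constant`), or
#' with different rates in the two halves (`different`).
#'
#' @param name one of `"study_null"`, `"study_pulse"`, `"pair_IM_early"`,
#'   `"pair_IM_different"`, `"pair_IM_constant"`, `"pair_IM_recent"`.
#' @param phi pulse proportion for `"study_pulse"`.
#' @param ... overrides passed to the pair template: `ne1`, `ne2`, `ne_anc`
#'   (diploid sizes), `t_split` (generations), `m` / `m_recent`, `m_old`
#'   (backwards migration rates per generation), `boundary` (epoch boundary,
#'   generations), `pulse` (an [ev_pulse()] between "P1" and "P2").
#' @return a [demographic_model()].
#' @export
scenario_preset <- function(name, phi = 0.1, ...) {
  valid <- c("study_null", "study_pulse", "pair_IM_early",
             "pair_IM_different", "pair_IM_constant", "pair_IM_recent")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    stop("unknown preset; valid presets: ", paste(valid, collapse = ", "))
  if (name %in% c("study_null", "study_pulse"))
    return(study_model(if (name == "study_null") 0 else phi))
  pair_im_model(name, ...)
}

# five-deme study system; times in generations (10-y generations)
study_model <- function(phi) {
  demes <- data.frame(
    name = c("HS", "TP_E", "TP_M", "TP_W", "J", "TP_EM", "TP", "ANC", "ROOT"),
    ne   = c(10000, 5000,  5000,  5000,  10000, 5000,  10000, 15000, 15000))
  nm <- demes$name
  m_contact <- 1e-5
  events <- list(
    ev_pulse(180, "HS", "TP_E", phi),
    ev_split(356, "TP_E", "TP_EM"),
    ev_split(356, "TP_M", "TP_EM"),
    ev_split(3693, "TP_EM", "TP"),
    ev_split(3693, "TP_W", "TP"),
    ev_migration(3693, mig_matrix(nm, list(list("HS", "TP", m_contact),
                                           list("TP", "HS", m_contact)))),
    ev_migration(14000, mig_matrix(nm)),
    ev_split(640000, "TP", "ANC"),
    ev_split(640000, "HS", "ANC"),
    ev_split(1280000, "ANC", "ROOT"),
    ev_split(1280000, "J", "ROOT"))
  demographic_model(demes, events)
}

pair_im_model <- function(name, ne1 = 5000, ne2 = 5000, ne_anc = 7500,
                          t_split = 4000, m = 5e-5, m_recent = NULL,
                          m_old = NULL, boundary = t_split / 2, pulse = NULL) {
  mr <- switch(name,
    pair_IM_constant = c(m, m),
    pair_IM_early    = c(0, m),
    pair_IM_recent   = c(m, 0),
    pair_IM_different = c(if (is.null(m_recent)) m else m_recent,
                          if (is.null(m_old)) m / 5 else m_old))
  demes <- data.frame(name = c("P1", "P2", "ANC"), ne = c(ne1, ne2, ne_anc))
  nm <- demes$name
  sym <- function(rate) mig_matrix(nm, list(list("P1", "P2", rate),
                                            list("P2", "P1", rate)))
  events <- list()
  if (mr[1] > 0) events <- c(events, list(ev_migration(0, sym(mr[1]))))
  if (!is.null(pulse)) events <- c(events, list(pulse))
  events <- c(events, list(ev_migration(boundary, sym(mr[2]))),
              list(ev_split(t_split, "P1", "ANC"),
                   ev_split(t_split, "P2", "ANC")))
  events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  demographic_model(demes, events)
}

# ---------------------------------------------------------------------------
# Simulation
# ---------------------------------------------------------------------------

# per-locus child seeds from one root seed (documented counter scheme);
# kept strictly below 2^31 - 1 for portability
locus_seeds <- function(seed, n)
  (as.numeric(seed) * 1000003 + 2 * seq_len(n)) %% 2147483647

#' Simulate a dataset under a demographic model
#'
#' Simulates `n_loci` independent non-recombining loci under the structured
#' coalescent defined by `model`, drops infinite-sites mutations as
#' Poisson(mu x branch length x locus length), and returns haplotype
#' genotypes with strictly increasing positions per contig. Loci are
#' distributed evenly over `n_contigs` contigs (laid end to end, so contig
#' length = loci per contig x `locus_length`). The ancestral allele is "A",
#' the derived allele "T" (arbitrary labels).
#'
#' Reproducibility: each locus gets a child seed derived from `seed` by a
#' fixed counter scheme, and a zero-proportion pulse event consumes no
#' randomness, so a model containing `phi = 0` events reproduces the stream
#' of the model without them.
#'
#' @param model a [demographic_model()].
#' @param sampling named integer vector of diploid sample counts per deme.
#' @param n_loci number of independent loci.
#' @param locus_length locus length in bp.
#' @param seed integer root seed.
#' @param n_contigs number of contigs the loci are assigned to.
#' @return an object of class `sim_dataset` with elements `hap_geno`
#'   (haplotypes x sites, 0 = ancestral / 1 = derived), `sites`
#'   (contig, pos, qual), `samples` (id, pop), `contigs` (name, length),
#'   `truth` (model, seed, per-locus TMRCA and branch lengths, pulse
#'   outcomes), and a missingness mask filled by [degrade_dataset()].
#' @export
simulate_dataset <- function(model, sampling, n_loci = 100,
                             locus_length = 300, seed, n_contigs = 1) {
  stopifnot(inherits(model, "demographic_model"))
  if (missing(seed)) stop("an explicit seed is required")
  if (is.null(names(sampling)) || any(!names(sampling) %in% model$demes$name))
    stop("sampling demes must be named and be a subset of model demes")
  sampling <- sampling[sampling > 0]
  nm <- model$demes$name
  nd <- length(nm)
  n_hap <- integer(nd); names(n_hap) <- nm
  n_hap[names(sampling)] <- 2L * as.integer(sampling)

  # flatten events; migration changes become a piecewise schedule
  sp <- Filter(function(e) e$type != "migration", model$events)
  mg <- Filter(function(e) e$type == "migration", model$events)
  ev_time <- vapply(sp, `[[`, numeric(1), "time")
  ev_type <- vapply(sp, function(e) if (e$type == "split") 0L else 1L, integer(1))
  ev_a <- vapply(sp, function(e)
    match(if (e$type == "split") e$child else e$source, nm) - 1L, integer(1))
  ev_b <- vapply(sp, function(e)
    match(if (e$type == "split") e$parent else e$dest, nm) - 1L, integer(1))
  ev_prop <- vapply(sp, function(e) if (e$type == "pulse") e$prop else 0, numeric(1))
  mig_times <- c(0, vapply(mg, `[[`, numeric(1), "time"))
  mig_mats <- c(list(matrix(0, nd, nd)),
                lapply(mg, function(e) {
                  r <- e$rates
                  if (!is.null(rownames(r))) r <- r[nm, nm, drop = FALSE]
                  unname(r)
                }))
  if (length(mig_times) > 1 && mig_times[2] == 0) { # change at t=0 replaces initial
    mig_times <- mig_times[-1]; mig_mats <- mig_mats[-1]
  }

  raw <- .sim_loci_cpp(n_hap, model$demes$ne, ev_time, ev_type, ev_a, ev_b,
                       ev_prop, mig_times, mig_mats, model$mutation_rate,
                       as.integer(locus_length), as.integer(n_loci),
                       locus_seeds(seed, n_loci))

  # contig layout: loci assigned contiguously, evenly
  per_contig <- ceiling(n_loci / n_contigs)
  locus_contig <- ((seq_len(n_loci) - 1) %/% per_contig) + 1
  locus_offset <- ((seq_len(n_loci) - 1) %% per_contig) * locus_length
  contig_names <- sprintf("chr%d", seq_len(max(locus_contig)))
  contig_len <- vapply(seq_along(contig_names), function(i)
    sum(locus_contig == i) * locus_length, numeric(1))

  sl <- raw$site_locus
  sites <- data.frame(
    contig = contig_names[locus_contig[sl]],
    pos = locus_offset[sl] + raw$site_pos,   # 1-based within contig
    qual = rep(60, length(sl)),
    stringsAsFactors = FALSE)

  pops <- rep(names(sampling), times = sampling)
  samples <- data.frame(
    id = paste0(pops, "_", unlist(lapply(sampling, seq_len))),
    pop = pops, stringsAsFactors = FALSE)

  pulses <- which(ev_type == 1L)
  truth <- list(seed = seed, model = model,
                sampling = sampling, n_loci = n_loci,
                locus_length = locus_length,
                tmrca = raw$tmrca, total_len = raw$total_len,
                pulse_present = raw$pulse_present[, pulses, drop = FALSE],
                pulse_moved = raw$pulse_moved[, pulses, drop = FALSE],
                degraded = FALSE)

  structure(list(hap_geno = raw$geno, sites = sites, samples = samples,
                 contigs = data.frame(name = contig_names, length = contig_len,
                                      stringsAsFactors = FALSE),
                 miss_mask = NULL, truth = truth),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$samples), " diploid samples (",
      nrow(x$hap_geno), " haplotypes), ", nrow(x$sites), " segregating sites, ",
      nrow(x$contigs), " contig(s)\n", sep = "")
  invisible(x)
}

#' Degrade a simulated dataset towards RAD-seq-like data
#'
#' Masks diploid genotype calls independently at `missing_rate` and draws a
#' per-site QUAL score from `qual_dist`. The truth record is updated.
#'
#' @param data a `sim_dataset`.
#' @param missing_rate per-call missingness probability in \[0, 1).
#' @param qual_dist either a single number (constant QUAL) or a
#'   `function(n)` returning `n` QUAL values.
#' @param seed integer seed.
#' @return the degraded `sim_dataset`.
#' @export
degrade_dataset <- function(data, missing_rate = 0.1,
                            qual_dist = function(n) round(rgamma(n, shape = 9, scale = 7), 1),
                            seed) {
  stopifnot(inherits(data, "sim_dataset"))
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (missing(seed)) stop("an explicit seed is required")
  n_samp <- nrow(data$samples); n_site <- nrow(data$sites)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647)
  if (missing_rate > 0) {
    mask <- matrix(runif(n_samp * n_site) < missing_rate, n_samp, n_site)
    data$miss_mask <- mask
  }
  data$sites$qual <- if (is.function(qual_dist)) qual_dist(n_site)
                     else rep(as.numeric(qual_dist), n_site)
  data$truth$degraded <- TRUE
  data$truth$missing_rate <- missing_rate
  data
}

.Random.seed_save <- function()
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Convert a simulated dataset to a genotype matrix
#'
#' Collapses haplotypes to diploid alt-allele dosages ({0, 1, 2}; masked
#' calls are `NA`), producing the same object [read_vcf()] returns. Sites
#' monomorphic in the sampled genotypes are retained (the simulator only
#' emits segregating sites).
#'
#' @param data a `sim_dataset`.
#' @return a `genotype_matrix` (see [read_vcf()]).
#' @export
as_genotype_matrix <- function(data) {
  stopifnot(inherits(data, "sim_dataset"))
  n <- nrow(data$samples)
  h <- data$hap_geno
  g <- h[seq(1, 2 * n, by = 2), , drop = FALSE] +
       h[seq(2, 2 * n, by = 2), , drop = FALSE]
  g <- t(g)  # sites x samples
  if (!is.null(data$miss_mask)) g[t(data$miss_mask)] <- NA_integer_
  colnames(g) <- data$samples$id
  sites <- data.frame(contig = data$sites$contig, pos = data$sites$pos,
                      qual = data$sites$qual, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  new_genotype_matrix(g, sites, data$samples, data$contigs)
}

# ---------------------------------------------------------------------------
# VCF writer
# ---------------------------------------------------------------------------

#' Write a simulated dataset as VCF plus population map
#'
#' Writes a VCFv4.2 file with GT genotypes and a QUAL column (masked calls
#' as `./.`), contig header lines, a two-column sample-to-population TSV,
#' and a JSON truth sidecar (`<path>.truth.json`) recording the simulation
#' seed and per-locus pulse outcomes. Round-trips losslessly through
#' [read_vcf()].
#'
#' @param data a `sim_dataset` with at least one site.
#' @param path output VCF path.
#' @param popmap_path output population-map TSV path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(data, path, popmap_path) {
  stopifnot(inherits(data, "sim_dataset"))
  if (nrow(data$sites) == 0) stop("dataset has no sites")
  n <- nrow(data$samples)
  h <- data$hap_geno
  a1 <- t(h[seq(1, 2 * n, by = 2), , drop = FALSE])
  a2 <- t(h[seq(2, 2 * n, by = 2), , drop = FALSE])
  gt <- matrix(paste0(a1, "/", a2), nrow(data$sites), n)
  if (!is.null(data$miss_mask)) gt[t(data$miss_mask)] <- "./."

  hdr <- c("##fileformat=VCFv4.2",
           "##source=introflow_coalsim",
           sprintf("##contig=<ID=%s,length=%d>", data$contigs$name,
                   as.integer(data$contigs$length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", data$samples$id), collapse = "\t"))
  body <- paste(data$sites$contig, data$sites$pos, ".", "A", "T",
                format(data$sites$qual, trim = TRUE, scientific = FALSE),
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  write.table(data$samples[, c("id", "pop")], popmap_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth <- data$truth
  truth$model <- NULL # not JSON-serializable; keep scalar summary instead
  truth$model_demes <- data$truth$model$demes
  truth$mutation_rate <- data$truth$model$mutation_rate
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
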