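# Genotype ingestion, variant filtering, allele frequencies and windows.
#
# Coordinates are 0-based half-open internally for window math (BED-like);
# VCF's 1-based positions are converted at the boundary. Site tables keep
# the original 1-based VCF position in `pos`.

new_genotype_matrix <- function(geno, sites, samples, contigs) {
  ord <- order(sites$contig, sites$pos)
  structure(list(geno = geno[ord, , drop = FALSE],
                 sites = sites[ord, , drop = FALSE],
                 samples = samples, contigs = contigs),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$sites), " biallelic SNPs x ",
      nrow(x$samples), " samples (", length(unique(x$samples$pop)),
      " populations)\n", sep = "")
  invisible(x)
}

#' Read a VCF and population map into a genotype matrix
#'
#' Ingests biallelic SNP records from a VCFv4.2 file (via `vcfR`) as
#' alt-allele dosage genotypes ({0, 1, 2}, missing preserved as `NA`),
#' together with a two-column sample-to-population TSV. Non-SNP and
#' multiallelic records are excluded and counted.
#'
#' @param vcf_path path to a VCF file.
#' @param popmap_path path to a TSV with columns sample, population (no
#'   header).
#' @return a `genotype_matrix`: list with `geno` (sites x samples dosage
#'   matrix), `sites` (contig, pos, qual, ref, alt), `samples` (id, pop),
#'   `contigs` (name, length), and attribute `excluded` (count of
#'   non-biallelic-SNP records).
#' @export
read_vcf <- function(vcf_path, popmap_path) {
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  if (!file.exists(popmap_path)) stop("population map not found: ", popmap_path)
  pm <- read.table(popmap_path, sep = "\t", header = FALSE,
                   col.names = c("id", "pop"), stringsAsFactors = FALSE)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samp <- colnames(v@gt)[-1]
  missing_pop <- setdiff(samp, pm$id)
  if (length(missing_pop))
    stop("sample absent from population map: ",
         paste(missing_pop, collapse = ", "))

  snp <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  excluded <- sum(!snp)

  gt <- vcfR::extract.gt(v, element = "GT")[snp, , drop = FALSE]
  # dosage: count of "1" alleles; anything containing "." is missing
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  idx <- match(gt, names(known))
  dos[] <- known[idx]
  colnames(dos) <- colnames(gt)

  qual <- suppressWarnings(as.numeric(fix[snp, "QUAL"]))
  sites <- data.frame(contig = fix[snp, "CHROM"],
                      pos = as.integer(fix[snp, "POS"]),
                      qual = qual,
                      ref = fix[snp, "REF"], alt = fix[snp, "ALT"],
                      stringsAsFactors = FALSE)

  # contig lengths from header when present, else max position
  meta <- v@meta
  cl <- regmatches(meta, regexec("##contig=<ID=([^,>]+),length=([0-9]+)", meta))
  cl <- Filter(function(x) length(x) == 3, cl)
  if (length(cl)) {
    contigs <- data.frame(name = vapply(cl, `[`, "", 2),
                          length = as.numeric(vapply(cl, `[`, "", 3)),
                          stringsAsFactors = FALSE)
  } else {
    agg <- tapply(sites$pos, sites$contig, max)
    contigs <- data.frame(name = names(agg), length = as.numeric(agg),
                          stringsAsFactors = FALSE)
  }
  samples <- data.frame(id = samp, pop = pm$pop[match(samp, pm$id)],
                        stringsAsFactors = FALSE)
  gm <- new_genotype_matrix(dos, sites, samples, contigs)
  attr(gm, "excluded") <- excluded
  gm
}

#' Apply the study's variant filters
#'
#' Retains sites with missing-call fraction strictly below `max_missing`,
#' QUAL strictly above `min_qual`, and overall minor-allele frequency
#' strictly above `min_maf` (computed from non-missing calls over all
#' samples jointly). The strict inequalities matter: a site at MAF exactly
#' 0.05 is excluded.
#'
#' @param gm a `genotype_matrix`.
#' @param max_missing maximum missing-call fraction (exclusive bound).
#' @param min_qual minimum QUAL (exclusive bound).
#' @param min_maf minimum minor-allele frequency (exclusive bound).
#' @return the filtered `genotype_matrix`; attribute `filter_counts` gives
#'   per-rule exclusion counts (a site failing several rules counts under
#'   each).
#' @export
filter_variants <- function(gm, max_missing = 0.20, min_qual = 30,
                            min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (max_missing < 0 || max_missing > 1) stop("max_missing must be in [0, 1]")
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must be in [0, 0.5]")
  g <- gm$geno
  n <- ncol(g)
  n_miss <- rowSums(is.na(g))
  miss_frac <- n_miss / n
  n_called <- 2 * (n - n_miss)
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / n_called, NA)
  maf <- pmin(p, 1 - p)
  qual <- gm$sites$qual

  fail_missing <- miss_frac >= max_missing
  fail_qual <- !(qual > min_qual) | is.na(qual)
  fail_maf <- !(maf > min_maf) | is.na(maf)
  keep <- !(fail_missing | fail_qual | fail_maf)

  out <- gm
  out$geno <- g[keep, , drop = FALSE]
  out$sites <- gm$sites[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(qual = sum(fail_qual),
                                  missing = sum(fail_missing),
                                  maf = sum(fail_maf))
  if (!any(keep)) warning("all sites removed by filters")
  out
}

#' Per-population derived-allele frequencies
#'
#' Computes per-site, per-population alt-allele frequencies and non-missing
#' allele counts. With `polarize_by_outgroup = TRUE` the outgroup
#' population's major allele is declared ancestral and frequencies are
#' flipped so that every `p` is a derived-allele frequency (after which the
#' outgroup frequency is at most 0.5). Sites with fewer than
#' `min_alleles_per_pop` non-missing alleles in any used population, or
#' with an exactly 50/50 outgroup (untiebreakable polarity), are dropped
#' and counted.
#'
#' @param gm a `genotype_matrix`.
#' @param roles named character vector mapping roles to population labels;
#'   for quartet statistics use names `P1`, `P2`, `P3`, `O`. Any role names
#'   are accepted; `O` designates the outgroup for polarization.
#' @param polarize_by_outgroup flip frequencies so `p` is derived.
#' @param min_alleles_per_pop minimum non-missing allele count per used
#'   population.
#' @return an `allele_freq_table`: list with `sites` (contig, pos), `p`
#'   (sites x roles derived/alt frequency matrix), `n` (allele counts),
#'   `roles`, `polarized`, and attribute `dropped` (counts by reason).
#' @export
allele_freqs <- function(gm, roles, polarize_by_outgroup = TRUE,
                         min_alleles_per_pop = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(names(roles))) stop("roles must be a named vector")
  bad <- setdiff(roles, unique(gm$samples$pop))
  if (length(bad)) stop("role population not in data: ", paste(bad, collapse = ", "))
  if (polarize_by_outgroup && !("O" %in% names(roles)))
    stop("polarization requested but no 'O' role given")

  p <- n <- matrix(NA_real_, nrow(gm$sites), length(roles),
                   dimnames = list(NULL, names(roles)))
  for (r in names(roles)) {
    cols <- gm$samples$pop == roles[[r]]
    sub <- gm$geno[, cols, drop = FALSE]
    nn <- 2 * rowSums(!is.na(sub))
    p[, r] <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / nn, NA)
    n[, r] <- nn
  }
  low <- apply(n, 1, function(x) any(x < min_alleles_per_pop))
  tie <- rep(FALSE, nrow(p))
  if (polarize_by_outgroup) tie <- !is.na(p[, "O"]) & p[, "O"] == 0.5
  keep <- !low & !tie & !apply(p, 1, anyNA)
  dropped <- c(low_count = sum(low), outgroup_tie = sum(tie & !low))
  p <- p[keep, , drop = FALSE]; n <- n[keep, , drop = FALSE]
  sites <- gm$sites[keep, c("contig", "pos")]
  if (polarize_by_outgroup && nrow(p)) {
    flip <- p[, "O"] > 0.5     # outgroup major allele is the ALT -> ancestral
    p[flip, ] <- 1 - p[flip, , drop = FALSE]
  }
  structure(list(sites = sites, p = p, n = n, roles = roles,
                 polarized = polarize_by_outgroup),
            class = "allele_freq_table", dropped = dropped)
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat("<allele_freq_table> ", nrow(x$p), " sites, roles: ",
      paste(names(x$roles), "=", x$roles, collapse = ", "),
      if (x$polarized) " (outgroup-polarized)", "\n", sep = "")
  invisible(x)
}

#' Re-polarize a genotype matrix by an outgroup population
#'
#' Flips REF/ALT dosages so that the REF allele is the ancestral state
#' inferred as the outgroup's major allele. Sites where the outgroup is
#' exactly 50/50 or has fewer than `min_alleles` called alleles are
#' dropped. Useful before [joint_sfs()] on empirical data.
#'
#' @param gm a `genotype_matrix`.
#' @param outgroup outgroup population label.
#' @param min_alleles minimum called outgroup alleles.
#' @return a `genotype_matrix` whose dosages count derived alleles.
#' @export
polarize_by_outgroup <- function(gm, outgroup, min_alleles = 2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cols <- gm$samples$pop == outgroup
  if (!any(cols)) stop("no samples in outgroup population: ", outgroup)
  sub <- gm$geno[, cols, drop = FALSE]
  nn <- 2 * rowSums(!is.na(sub))
  po <- ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / nn, NA)
  keep <- !is.na(po) & nn >= min_alleles & po != 0.5
  out <- gm
  out$geno <- gm$geno[keep, , drop = FALSE]
  out$sites <- gm$sites[keep, , drop = FALSE]
  flip <- po[keep] > 0.5
  out$geno[flip, ] <- 2L - out$geno[flip, , drop = FALSE]
  ra <- out$sites$ref[flip]
  out$sites$ref[flip] <- out$sites$alt[flip]
  out$sites$alt[flip] <- ra
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Tile contigs into fixed-width windows
#'
#' Produces a half-open (0-based) tiling of each contig; the trailing
#' partial window is discarded, so a 25-kb contig yields exactly two 10-kb
#' windows.
#'
#' @param contigs data.frame with columns `name`, `length`.
#' @param width window width in bp.
#' @param step step between window starts (defaults to `width`,
#'   non-overlapping).
#' @return data.frame with columns `contig`, `start` (0-based, inclusive),
#'   `end` (exclusive), `width`.
#' @export
make_windows <- function(contigs, width = 10000, step = width) {
  stopifnot(width > 0, step > 0)
  out <- lapply(seq_len(nrow(contigs)), function(i) {
    L <- contigs$length[i]
    starts <- seq(0, L, by = step)
    starts <- starts[starts + width <= L]
    if (!length(starts)) return(NULL)
    data.frame(contig = contigs$name[i], start = starts,
               end = starts + width, width = width,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), width = numeric(0))
  rownames(out) <- NULL
  out
}

# index of the window containing each (contig, pos); pos is 1-based VCF,
# windows half-open 0-based, so pos p falls in [start, end) iff
# start < p <= end
window_index <- function(windows, contig, pos) {
  idx <- rep(NA_integer_, length(pos))
  for (ct in unique(windows$contig)) {
    w <- which(windows$contig == ct)
    s <- which(contig == ct)
    if (!length(s)) next
    j <- findInterval(pos[s] - 1, windows$start[w])
    ok <- j >= 1 & j <= length(w)
    ok[ok] <- pos[s][ok] - 1 < windows$end[w][j[ok]]
    idx[s[ok]] <- w[j[ok]]
  }
  idx
}
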