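# ABBA-BABA / f_dM / f3 statistics with block-jackknife inference.
#
# Sign conventions (one table, used everywhere):
#   D(P1, P2; P3, O)  > 0  : excess allele sharing P2 <-> P3
#   D(P1, P2; P3, O)  < 0  : excess allele sharing P1 <-> P3
#   f_dM              > 0  : P2 <-> P3 sharing; < 0 : P1 <-> P3 sharing
#   f3(C; A, B) significantly < 0 : C is admixed between A-like and B-like
# All statistics are frequency-based (deterministic given the frequency
# table), not single-read-sampled.

#' Per-site ABBA and BABA pattern weights
#'
#' From outgroup-polarized derived-allele frequencies (p1, p2, p3, p4),
#' computes `abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`.
#' Degenerate sites (e.g. p3 = 0) contribute zeros.
#'
#' @param freqs an `allele_freq_table` with roles `P1`, `P2`, `P3`, `O`.
#' @return data.frame with columns `contig`, `pos`, `abba`, `baba`.
#' @export
site_patterns <- function(freqs) {
  p <- quartet_freqs(freqs)
  data.frame(contig = freqs$sites$contig, pos = freqs$sites$pos,
             abba = (1 - p[, 1]) * p[, 2] * p[, 3] * (1 - p[, 4]),
             baba = p[, 1] * (1 - p[, 2]) * p[, 3] * (1 - p[, 4]),
             stringsAsFactors = FALSE)
}

quartet_freqs <- function(freqs, roles = c("P1", "P2", "P3", "O")) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  if (!all(roles %in% colnames(freqs$p)))
    stop("frequency table lacks roles: ",
         paste(setdiff(roles, colnames(freqs$p)), collapse = ", "))
  if (!freqs$polarized) stop("polarized frequencies required")
  freqs$p[, roles, drop = FALSE]
}

#' Weighted delete-one-block jackknife
#'
#' The estimate is the weighted mean of per-block values; its standard
#' error comes from delete-one-block pseudovalues with Busing-style
#' weighting. For a ratio statistic such as Patterson's D, passing block
#' ratios with the block denominators as weights makes the weighted mean
#' equal the genome-wide ratio of sums. With equal weights the SE reduces
#' to the classical `s/sqrt(n)` of the sample mean.
#'
#' @param values per-block statistic values.
#' @param weights per-block weights (default equal).
#' @return list with `estimate`, `se`, `z`, `n_blocks`.
#' @export
block_jackknife <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  if (n < 2) stop("at least 2 blocks required")
  if (length(weights) != n) stop("values and weights differ in length")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  W <- sum(weights)
  est <- sum(weights * values) / W
  loo <- (W * est - weights * values) / (W - weights)  # delete-one estimates
  h <- W / weights
  ps <- h * est - (h - 1) * loo                         # pseudovalues
  theta_j <- n * est - sum((1 - weights / W) * loo)
  v <- sum((ps - theta_j)^2 / (h - 1)) / n
  se <- sqrt(v)
  list(estimate = est, se = se,
       z = if (se > 0) est / se else if (est == 0) 0 else Inf,
       n_blocks = n)
}

# cut sites into consecutive blocks of `block_size` sites (per contig when
# contig-local), dropping blocks with zero weight
site_blocks <- function(n_sites, block_size)
  ((seq_len(n_sites) - 1) %/% block_size) + 1

#' Patterson's D with block-jackknife significance
#'
#' D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA) over all sites, with a
#' weighted delete-one-block jackknife over consecutive blocks of
#' `block_size_snps` sites (block weight = informative content
#' ABBA + BABA) giving SE and Z = D/SE. Z > 3 is the conventional
#' significance indicator for P2-P3 excess sharing.
#'
#' @param freqs an `allele_freq_table` with roles `P1`, `P2`, `P3`, `O`.
#' @param block_size_snps sites per jackknife block.
#' @param weighted use informative-site weights (default) or equal weights.
#' @return a `dstat_result`: list with `d`, `se`, `z`, `abba`, `baba`,
#'   `n_blocks`, `n_informative_sites`, `significant` (Z > 3).
#' @export
patterson_d <- function(freqs, block_size_snps = 1000, weighted = TRUE) {
  sp <- site_patterns(freqs)
  dstat_from_patterns(sp$abba, sp$baba, block_size_snps, weighted)
}

dstat_from_patterns <- function(abba, baba, block_size_snps, weighted = TRUE) {
  num <- abba - baba
  den <- abba + baba
  if (sum(den) <= 0) stop("undefined D: no informative sites (zero denominator)")
  blk <- site_blocks(length(den), block_size_snps)
  bd <- tapply(den, blk, sum)
  bn <- tapply(num, blk, sum)
  keep <- bd > 0
  bd <- bd[keep]; bn <- bn[keep]
  if (length(bd) < 2) stop("need at least 2 non-empty jackknife blocks")
  jk <- block_jackknife(bn / bd, if (weighted) bd else rep(1, length(bd)))
  if (jk$se == 0 && jk$estimate != 0)
    warning("degenerate jackknife: SE = 0 with non-zero D; Z reported as Inf")
  structure(list(d = jk$estimate, se = jk$se, z = jk$z,
                 abba = sum(abba), baba = sum(baba),
                 n_blocks = jk$n_blocks,
                 n_informative_sites = sum(den > 0),
                 significant = is.finite(jk$z) && jk$z > 3 || jk$z == Inf),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D = %.4f  SE = %.4f  Z = %.2f  (ABBA = %.1f, BABA = %.1f, %d blocks)\n",
              x$d, x$se, x$z, x$abba, x$baba, x$n_blocks))
  invisible(x)
}

#' Per-contig D-statistic scan
#'
#' Runs [patterson_d()] separately on each contig with contig-local
#' jackknife blocks. Contigs with fewer than 2 non-empty blocks (or no
#' informative sites) are reported as untested.
#'
#' @param freqs an `allele_freq_table` with quartet roles.
#' @param contigs contig names to test (default: all present).
#' @param block_size_snps sites per jackknife block.
#' @return data.frame with one row per contig: `contig`, `d`, `se`, `z`,
#'   `n_informative_sites`, `status` ("tested"/"untested"), `significant`.
#' @export
chrom_scan_d <- function(freqs, contigs = unique(freqs$sites$contig),
                         block_size_snps = 1000) {
  rows <- lapply(contigs, function(ct) {
    keep <- freqs$sites$contig == ct
    sub <- freqs
    sub$sites <- freqs$sites[keep, , drop = FALSE]
    sub$p <- freqs$p[keep, , drop = FALSE]
    sub$n <- freqs$n[keep, , drop = FALSE]
    r <- tryCatch(patterson_d(sub, block_size_snps),
                  error = function(e) NULL)
    if (is.null(r))
      data.frame(contig = ct, d = NA, se = NA, z = NA,
                 n_informative_sites = 0L, status = "untested",
                 significant = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(contig = ct, d = r$d, se = r$se, z = r$z,
                 n_informative_sites = r$n_informative_sites,
                 status = "tested", significant = isTRUE(r$significant),
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# f_dM donor-substitution denominator for one site (vectorized over sites)
fdm_components <- function(p1, p2, p3, p4) {
  abba <- function(a, b, c, d) (1 - a) * b * c * (1 - d)
  baba <- function(a, b, c, d) a * (1 - b) * c * (1 - d)
  num <- abba(p1, p2, p3, p4) - baba(p1, p2, p3, p4)
  pd2 <- pmax(p2, p3)
  pd1 <- pmax(p1, p3)
  den <- ifelse(p2 >= p1,
                abba(p1, pd2, pd2, p4) - baba(p1, pd2, pd2, p4),
                -(abba(pd1, p2, pd1, p4) - baba(pd1, p2, pd1, p4)))
  list(num = num, den = den)
}

#' Windowed f_dM introgression scan
#'
#' For each window, f_dM = sum(n_i) / sum(d_i) over the window's sites,
#' where n_i = ABBA_i - BABA_i and d_i substitutes the donor frequency
#' p_D = max(p2, p3) into both the P2 and P3 slots when p2 >= p1, and
#' p_D = max(p1, p3) into the P1 and P3 slots (negated) otherwise. f_dM is
#' bounded in \[-1, 1\] and symmetric: positive values indicate P2-P3
#' sharing, negative P1-P3. Windows with fewer than `min_sites` usable
#' sites, or a zero denominator, are omitted and counted.
#'
#' @param freqs an `allele_freq_table` with roles `P1`, `P2`, `P3`, `O`.
#' @param windows window table from [make_windows()].
#' @param min_sites minimum usable sites per retained window.
#' @return data.frame with `contig`, `start`, `end`, `n_sites_used`,
#'   `numerator`, `denominator`, `fdm`; attribute `omitted` (windows
#'   dropped by the min-sites and zero-denominator rules).
#' @export
fdm_windows <- function(freqs, windows, min_sites = 5) {
  p <- quartet_freqs(freqs)
  comp <- fdm_components(p[, 1], p[, 2], p[, 3], p[, 4])
  widx <- window_index(windows, freqs$sites$contig, freqs$sites$pos)
  use <- !is.na(widx)
  if (!any(use)) {
    out <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), n_sites_used = integer(0),
                      numerator = numeric(0), denominator = numeric(0),
                      fdm = numeric(0))
    attr(out, "omitted") <- c(min_sites = 0, zero_denominator = 0)
    return(out)
  }
  num <- tapply(comp$num[use], widx[use], sum)
  den <- tapply(comp$den[use], widx[use], sum)
  nst <- tapply(comp$num[use], widx[use], length)
  w <- as.integer(names(num))
  ok <- nst >= min_sites & den != 0
  out <- data.frame(contig = windows$contig[w[ok]],
                    start = windows$start[w[ok]],
                    end = windows$end[w[ok]],
                    n_sites_used = as.integer(nst[ok]),
                    numerator = as.numeric(num[ok]),
                    denominator = as.numeric(den[ok]),
                    fdm = as.numeric(num[ok] / den[ok]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "omitted") <- c(min_sites = sum(nst < min_sites),
                            zero_denominator = sum(nst >= min_sites & den == 0))
  out
}

#' Top-quantile f_dM outlier windows
#'
#' The threshold is the empirical `quantile` (type-7 interpolation) of the
#' window f_dM values; outliers are windows strictly above it (ties at the
#' threshold are excluded).
#'
#' @param results output of [fdm_windows()].
#' @param quantile quantile defining the outlier threshold.
#' @return list with `threshold` and `outliers` (subset of `results`).
#' @export
fdm_outliers <- function(results, quantile = 0.95) {
  if (!nrow(results)) stop("no f_dM windows supplied")
  thr <- stats::quantile(results$fdm, probs = quantile, type = 7,
                         names = FALSE)
  list(threshold = thr, outliers = results[results$fdm > thr, , drop = FALSE])
}

#' f3 admixture statistic
#'
#' f3(C; A, B) is the mean over sites of (c - a)(c - b) using population
#' allele frequencies; a significantly negative value (Z < -3 by block
#' jackknife, default blocks of 500 SNPs) indicates that C is admixed
#' between A-like and B-like sources. No finite-sample heterozygosity
#' correction is applied (conservative against false positives).
#'
#' @param freqs an `allele_freq_table` with roles `C`, `A`, `B` (any
#'   additional roles ignored). Polarization is irrelevant for f3.
#' @param block_size_snps sites per jackknife block.
#' @return an `f3_result`: list with `f3`, `se`, `z`, `n_blocks`,
#'   `n_sites`, `call` ("admixed" when Z < -3, else "not admixed").
#' @export
f3_stat <- function(freqs, block_size_snps = 500) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  need <- c("C", "A", "B")
  if (!all(need %in% colnames(freqs$p)))
    stop("frequency table must carry roles C, A, B")
  cc <- freqs$p[, "C"]; aa <- freqs$p[, "A"]; bb <- freqs$p[, "B"]
  term <- (cc - aa) * (cc - bb)
  blk <- site_blocks(length(term), block_size_snps)
  bv <- tapply(term, blk, mean)
  bw <- tapply(term, blk, length)
  if (length(bv) < 2) stop("at least 2 blocks required")
  jk <- block_jackknife(as.numeric(bv), as.numeric(bw))
  structure(list(f3 = jk$estimate, se = jk$se, z = jk$z,
                 n_blocks = jk$n_blocks, n_sites = length(term),
                 call = if (is.finite(jk$z) && jk$z < -3) "admixed"
                        else "not admixed"),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf("f3 = %.5f  SE = %.5f  Z = %.2f  -> %s\n",
              x$f3, x$se, x$z, x$call))
  invisible(x)
}
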