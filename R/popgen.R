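# Windowed diversity/differentiation statistics, neutrality tests, LD decay
# and the Z(FST) / log10(theta-pi ratio) selection scan.
#
# pi uses accessible-site denominators: the per-window mean is taken over
# the genotyped SNP sites in the window (sparse reduced-representation data
# make fixed physical denominators misleading); SNP density relates counts
# to physical window width instead.

pop_site_freqs <- function(gm, pop) {
  cols <- gm$samples$pop == pop
  if (!any(cols)) stop("no samples in population: ", pop)
  sub <- gm$geno[, cols, drop = FALSE]
  nn <- 2 * rowSums(!is.na(sub))
  list(p = ifelse(nn > 0, rowSums(sub, na.rm = TRUE) / nn, NA), n = nn,
       het_obs = rowMeans(sub == 1, na.rm = TRUE))
}

#' Windowed diversity and differentiation statistics
#'
#' Per window and population: nucleotide diversity pi (per-site expected
#' heterozygosity with the `n/(n-1)` sample-size correction, averaged over
#' genotyped sites), observed and expected heterozygosity, SNP density
#' (segregating sites / window width) and Tajima's D. Per population pair:
#' Dxy (mean per-site `px(1-py) + py(1-px)`) and Hudson's FST as a
#' ratio of averages, `1 - mean(H_within) / mean(H_between)`, where
#' H_within averages the two populations' expected heterozygosities
#' (uncorrected `2p(1-p)`, so that identical frequency vectors give
#' exactly FST = 0; the bias-corrected within-population diversity is
#' reported separately as pi).
#'
#' @param gm a `genotype_matrix`.
#' @param populations population labels to analyze (default: all).
#' @param windows window table from [make_windows()].
#' @return data.frame with one row per window: `contig`, `start`, `end`,
#'   `n_sites`, then `pi_<pop>`, `ho_<pop>`, `he_<pop>`, `tajima_d_<pop>`,
#'   `snp_density`, and `dxy_<a>_<b>` / `fst_<a>_<b>` per pair. Windows
#'   with no genotyped sites keep `n_sites = 0` and `NA` statistics.
#' @export
window_diversity <- function(gm, populations = unique(gm$samples$pop),
                             windows) {
  stopifnot(inherits(gm, "genotype_matrix"))
  fr <- lapply(populations, function(p) pop_site_freqs(gm, p))
  names(fr) <- populations
  widx <- window_index(windows, gm$sites$contig, gm$sites$pos)

  nw <- nrow(windows)
  wmean <- function(x, use) {  # per-window mean over usable sites
    out <- rep(NA_real_, nw)
    u <- use & !is.na(widx)
    if (!any(u)) return(out)
    s <- tapply(x[u], widx[u], mean)
    out[as.integer(names(s))] <- as.numeric(s)
    out
  }
  wcount <- function(use) {
    out <- rep(0L, nw)
    u <- use & !is.na(widx)
    if (!any(u)) return(out)
    s <- tapply(u[u], widx[u], length)
    out[as.integer(names(s))] <- as.integer(s)
    out
  }

  res <- data.frame(contig = windows$contig, start = windows$start,
                    end = windows$end, stringsAsFactors = FALSE)
  any_called <- rowSums(!is.na(gm$geno)) > 0
  res$n_sites <- wcount(any_called)

  het <- list()
  for (p in populations) {
    f <- fr[[p]]
    ok <- f$n >= 2
    h <- ifelse(ok, 2 * f$p * (1 - f$p) * f$n / (f$n - 1), NA)
    het[[p]] <- h
    res[[paste0("pi_", p)]] <- wmean(h, ok)
    res[[paste0("ho_", p)]] <- wmean(f$het_obs, ok)
    res[[paste0("he_", p)]] <- wmean(2 * f$p * (1 - f$p), ok)
    res[[paste0("tajima_d_", p)]] <- window_tajima(gm, p, widx, nw)
  }
  res$snp_density <- res$n_sites / windows$width

  if (length(populations) >= 2) {
    prs <- utils::combn(populations, 2, simplify = FALSE)
    for (pr in prs) {
      fa <- fr[[pr[1]]]; fb <- fr[[pr[2]]]
      ok <- fa$n >= 2 & fb$n >= 2
      dxy <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
      hw <- (2 * fa$p * (1 - fa$p) + 2 * fb$p * (1 - fb$p)) / 2
      res[[paste0("dxy_", pr[1], "_", pr[2])]] <- wmean(dxy, ok)
      mhw <- wmean(hw, ok); mhb <- wmean(dxy, ok)
      res[[paste0("fst_", pr[1], "_", pr[2])]] <-
        ifelse(mhb > 0, 1 - mhw / mhb, NA)
    }
  }
  rownames(res) <- NULL
  res
}

window_tajima <- function(gm, pop, widx, nw) {
  cols <- gm$samples$pop == pop
  sub <- gm$geno[, cols, drop = FALSE]
  out <- rep(NA_real_, nw)
  for (w in unique(widx[!is.na(widx)])) {
    g <- sub[which(widx == w), , drop = FALSE]
    cnt <- site_counts_from_geno(g)
    if (is.null(cnt) || cnt$n < 4 || cnt$S < 1) next
    out[w] <- tajimas_d(cnt)
  }
  out
}

#' Site-count summaries for neutrality tests
#'
#' Builds the (n, S, eta, eta_e, pi_abs) summary that Tajima's D and Fu &
#' Li's tests consume, from derived-allele dosage genotypes of one
#' population (REF assumed ancestral, as after [polarize_by_outgroup()] or
#' from the simulator). Sample size n is taken as the median non-missing
#' allele count across sites (sites at other depths are used as-is;
#' suitable for near-complete data). `eta_e` counts derived singletons,
#' `eta_s` singletons of either allele, `pi_abs` the mean pairwise
#' difference summed over sites.
#'
#' @param n number of haplotypes.
#' @param S segregating sites.
#' @param eta total mutations (infinite sites: `eta = S`).
#' @param eta_e external (derived-singleton) mutations.
#' @param eta_s singleton mutations of either allele.
#' @param pi_abs sum over sites of mean pairwise differences.
#' @return a `site_counts` list.
#' @export
site_counts <- function(n, S, eta = S, eta_e = NA, eta_s = NA, pi_abs) {
  if (!is.na(eta_e) && eta_e > eta) stop("eta_e cannot exceed eta")
  if (S > eta) stop("S cannot exceed eta")
  structure(list(n = n, S = S, eta = eta, eta_e = eta_e, eta_s = eta_s,
                 pi_abs = pi_abs), class = "site_counts")
}

site_counts_from_geno <- function(g) {
  nn <- 2 * rowSums(!is.na(g))
  d <- rowSums(g, na.rm = TRUE)
  seg <- d > 0 & d < nn & nn >= 2
  if (!any(seg)) return(NULL)
  nn <- nn[seg]; d <- d[seg]
  n <- as.integer(stats::median(nn))
  p <- d / nn
  pi_abs <- sum(2 * p * (1 - p) * nn / (nn - 1))
  site_counts(n = n, S = sum(seg), eta = sum(seg),
              eta_e = sum(d == 1), eta_s = sum(d == 1 | d == nn - 1),
              pi_abs = pi_abs)
}

#' Tajima's D
#'
#' The 1989 estimator `D = (pi_abs - S/a1) / sqrt(e1 S + e2 S (S - 1))`
#' with the standard constants of the sample size n. Negative values flag
#' an excess of rare variants.
#'
#' @param counts a [site_counts()] object with `n >= 4`.
#' @return the statistic, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(counts) {
  stopifnot(inherits(counts, "site_counts"))
  n <- counts$n; S <- counts$S
  if (n < 4) stop("Tajima's D requires n >= 4 haplotypes")
  if (S < 1) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (counts$pi_abs - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu and Li's neutrality tests
#'
#' The 1993 D and F statistics contrast total mutations with external
#' (derived-singleton) mutations, requiring outgroup polarization; the
#' starred variants D* and F* use singletons of either allele and need no
#' outgroup. All use the published normalizing constants.
#'
#' @param counts a [site_counts()] object (`eta_e` required for D/F,
#'   `eta_s` for D*/F*).
#' @param variant one of `"D"`, `"F"`, `"D*"`, `"F*"`.
#' @return the statistic, or `NA` when `eta = 0`.
#' @export
fu_li <- function(counts, variant = c("D", "F", "D*", "F*")) {
  stopifnot(inherits(counts, "site_counts"))
  variant <- match.arg(variant)
  n <- counts$n; eta <- counts$eta
  if (n < 4) stop("Fu & Li tests require n >= 4 haplotypes")
  if (eta < 1) return(NA_real_)
  a <- sum(1 / seq_len(n - 1))
  b <- sum(1 / seq_len(n - 1)^2)
  an1 <- a + 1 / n
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  if (variant %in% c("D", "F")) {
    if (is.na(counts$eta_e)) stop("eta_e (external mutations) required for D/F")
  } else if (is.na(counts$eta_s)) stop("eta_s (singletons) required for D*/F*")

  if (variant == "D") {
    vD <- 1 + a^2 / (b + a^2) * (cn - (n + 1) / (n - 1))
    uD <- a - 1 - vD
    return((eta - a * counts$eta_e) / sqrt(uD * eta + vD * eta^2))
  }
  if (variant == "F") {
    vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a^2 + b)
    uF <- (1 + (n + 1) / (3 * (n - 1)) -
             4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vF
    return((counts$pi_abs - counts$eta_e) / sqrt(uF * eta + vF * eta^2))
  }
  dn <- cn + (n - 2) / (n - 1)^2 +
    2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  if (variant == "D*") {
    vDs <- ((n / (n - 1))^2 * b + a^2 * dn -
              2 * n * a * (a + 1) / (n - 1)^2) / (a^2 + b)
    uDs <- (n / (n - 1)) * (a - n / (n - 1)) - vDs
    return((n / (n - 1) * eta - a * counts$eta_s) /
             sqrt(uDs * eta + vDs * eta^2))
  }
  vFs <- (dn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) -
            2 / (n - 1) * (4 * b - 6 + 8 / n)) / (a^2 + b)
  uFs <- (n / (n - 1) + (n + 1) / (3 * (n - 1)) - 4 / (n * (n - 1)) +
            2 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / a - vFs
  (counts$pi_abs - (n - 1) / n * counts$eta_s) /
    sqrt(uFs * eta + vFs * eta^2)
}

#' Linkage-disequilibrium decay curve
#'
#' Computes composite (genotype-dosage correlation, no phasing) r-squared
#' for all intra-contig SNP pairs at distance at most `max_dist_bp`, bins
#' the pairs by distance, and reports per-bin mean r-squared together with
#' the half-decay distance: the smallest bin midpoint whose mean r-squared
#' has fallen to half of the maximum bin mean.
#'
#' @param gm a `genotype_matrix`.
#' @param population population label.
#' @param max_dist_bp maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return an `ld_decay_curve`: data.frame (`bin_start`, `bin_end`,
#'   `mid`, `mean_r2`, `n_pairs`) with attribute `half_decay_bp`.
#' @export
ld_decay <- function(gm, population, max_dist_bp = 5000,
                     bin_width = max(1, round(max_dist_bp / 20))) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cols <- gm$samples$pop == population
  if (!any(cols)) stop("no samples in population: ", population)
  g <- gm$geno[, cols, drop = FALSE]
  d <- numeric(0); r2 <- numeric(0)
  for (ct in unique(gm$sites$contig)) {
    s <- which(gm$sites$contig == ct)
    if (length(s) < 2) next
    pos <- gm$sites$pos[s]
    for (i in seq_len(length(s) - 1)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_dist_bp)
      j <- j[j > i]
      if (!length(j)) next
      xi <- g[s[i], ]
      for (k in j) {
        xk <- g[s[k], ]
        ok <- !is.na(xi) & !is.na(xk)
        if (sum(ok) < 3 || var(xi[ok]) == 0 || var(xk[ok]) == 0) next
        d <- c(d, pos[k] - pos[i])
        r2 <- c(r2, stats::cor(xi[ok], xk[ok])^2)
      }
    }
  }
  if (!length(d)) stop("no usable SNP pairs within max_dist_bp")
  bin <- pmin(floor((d - 1) / bin_width), ceiling(max_dist_bp / bin_width) - 1)
  mean_r2 <- tapply(r2, bin, mean)
  n_pairs <- tapply(r2, bin, length)
  b <- as.integer(names(mean_r2))
  curve <- data.frame(bin_start = b * bin_width, bin_end = (b + 1) * bin_width,
                      mid = (b + 0.5) * bin_width,
                      mean_r2 = as.numeric(mean_r2),
                      n_pairs = as.integer(n_pairs))
  curve <- curve[order(curve$bin_start), ]
  rownames(curve) <- NULL
  half <- curve$mid[curve$mean_r2 <= max(curve$mean_r2) / 2]
  attr(curve, "half_decay_bp") <- if (length(half)) min(half) else NA_real_
  class(curve) <- c("ld_decay_curve", "data.frame")
  curve
}

#' Z(FST) / log10(theta-pi ratio) selection scan
#'
#' Z-transforms per-window FST values and takes log10 of the pi ratio
#' (group 1 over group 2); candidate outliers are windows in the top
#' `1 - quantile` tail of both scores (`mode = "both"`, the default
#' conjunction rule) or of either (`mode = "either"`). Windows with zero
#' or missing denominator pi are excluded from the ratio ranking and
#' counted.
#'
#' @param fst per-window FST values.
#' @param pi1,pi2 per-window pi for the two groups (aligned with `fst`).
#' @param windows aligned window table ([make_windows()] subset).
#' @param quantile outlier quantile (default top 5%).
#' @param mode `"both"` (conjunction) or `"either"` (union).
#' @return list with `scores` (windows + `z_fst`, `log10_pi_ratio`,
#'   `outlier`), `outliers` (subset), thresholds, and `n_excluded`.
#' @export
selection_scan <- function(fst, pi1, pi2, windows, quantile = 0.95,
                           mode = c("both", "either")) {
  mode <- match.arg(mode)
  stopifnot(length(fst) == nrow(windows), length(pi1) == length(fst),
            length(pi2) == length(fst))
  usable <- !is.na(fst) & !is.na(pi1) & !is.na(pi2) & pi2 > 0
  n_excluded <- sum(!usable)
  z <- (fst - mean(fst[usable])) / sd(fst[usable])
  lr <- log10(pi1 / pi2)
  zt <- stats::quantile(z[usable], quantile, type = 7, names = FALSE)
  lt <- stats::quantile(lr[usable], quantile, type = 7, names = FALSE)
  hit_z <- usable & z > zt
  hit_l <- usable & lr > lt
  out <- if (mode == "both") hit_z & hit_l else hit_z | hit_l
  scores <- cbind(windows,
                  data.frame(z_fst = z, log10_pi_ratio = lr, outlier = out))
  list(scores = scores, outliers = scores[out, , drop = FALSE],
       z_fst_threshold = zt, log10_ratio_threshold = lt,
       n_excluded = n_excluded)
}
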