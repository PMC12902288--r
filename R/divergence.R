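# Pairwise codon-level Ka/Ks by Nei-Gojobori (1986) counting with
# Jukes-Cantor correction, a substitution-count contingency test, and the
# molecular-clock conversion T = K_S / (2 r).

# standard (universal) genetic code
GENETIC_CODE_STD <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

translate_codon <- function(codon) GENETIC_CODE_STD[[codon]]

# NG86 synonymous site count for one codon: at each position, the fraction
# of the three possible changes that are synonymous; changes creating a
# stop codon count as nonsynonymous, so every codon contributes exactly 3
# sites split between S and N.
codon_syn_sites <- function(codon) {
  nts <- c("T", "C", "A", "G")
  aa0 <- translate_codon(codon)
  s <- 0
  for (i in 1:3) {
    for (nt in setdiff(nts, substr(codon, i, i))) {
      alt <- codon
      substr(alt, i, i) <- nt
      if (translate_codon(alt) == aa0 && aa0 != "*") s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged syn/nonsyn differences between two codons; all minimal
# mutational pathways weighted equally, pathways passing through a stop
# codon discarded (all-blocked pairs fall back to equal weighting over all)
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(nd = 0, sd = 0))
  orders <- if (d == 1) list(1L) else combinat_perms(d)
  paths <- list()
  for (ord in orders) {
    cur <- c1
    steps <- character(0)
    blocked <- FALSE
    for (k in ord) {
      nxt <- cur
      substr(nxt, pos[k], pos[k]) <- substr(c2, pos[k], pos[k])
      steps <- c(steps, paste(cur, nxt))
      if (translate_codon(nxt) == "*" && nxt != c2) blocked <- TRUE
      cur <- nxt
    }
    paths[[length(paths) + 1]] <- list(steps = steps, blocked = blocked)
  }
  usable <- Filter(function(p) !p$blocked, paths)
  if (!length(usable)) usable <- paths
  nd <- sd <- 0
  for (p in usable) {
    for (st in p$steps) {
      cds <- strsplit(st, " ")[[1]]
      syn <- translate_codon(cds[1]) == translate_codon(cds[2]) &&
        translate_codon(cds[1]) != "*"
      if (syn) sd <- sd + 1 else nd <- nd + 1
    }
  }
  c(nd = nd / length(usable), sd = sd / length(usable))
}

combinat_perms <- function(d) {
  if (d == 1) return(list(1L))
  out <- list()
  rec <- function(prefix, rest) {
    if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(d))
  out
}

#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting
#'
#' For a gap-free codon alignment of two sequences: per-codon synonymous /
#' nonsynonymous site fractions from the universal genetic code (changes to
#' stop codons count as nonsynonymous, so N + S equals the alignment
#' length); differences averaged over equally weighted minimal mutational
#' pathways (pathways through stop codons discarded); Jukes-Cantor
#' correction `-(3/4) log(1 - (4/3) p)` applied to pN and pS; and a
#' two-sided Fisher exact test on the 2x2 table
#' `{(Nd, N - Nd), (Sd, S - Sd)}` (counts rounded half-up for the test
#' only).
#'
#' @param pair character vector of two nucleotide sequences (equal length,
#'   divisible by 3, no gaps or internal stop codons), or a list of two.
#' @return a `kaks_result`: list with `ka`, `ks`, `omega` (`NA` when
#'   `ks = 0` or a correction is undefined), `N`, `S`, `Nd`, `Sd`,
#'   `p_fisher`.
#' @export
kaks_ng86 <- function(pair) {
  pair <- toupper(unlist(pair))
  if (length(pair) != 2) stop("exactly two sequences required")
  s1 <- gsub("\\s", "", pair[1]); s2 <- gsub("\\s", "", pair[2])
  if (nchar(s1) != nchar(s2)) stop("sequences differ in length")
  if (nchar(s1) %% 3 != 0) stop("alignment length not divisible by 3")
  if (grepl("-", paste0(s1, s2))) stop("gap characters present; supply gap-free codons")
  nc <- nchar(s1) / 3
  cod1 <- substring(s1, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  cod2 <- substring(s2, 3 * seq_len(nc) - 2, 3 * seq_len(nc))
  for (i in seq_len(nc)) {
    for (cd in c(cod1[i], cod2[i])) {
      if (!cd %in% names(GENETIC_CODE_STD))
        stop("invalid codon at index ", i, ": ", cd)
      if (translate_codon(cd) == "*" && i < nc)
        stop("internal stop codon at index ", i)
    }
  }
  S <- sum(vapply(cod1, codon_syn_sites, numeric(1)) +
             vapply(cod2, codon_syn_sites, numeric(1))) / 2
  N <- 3 * nc - S
  diffs <- mapply(function(a, b) codon_path_diffs(a, b), cod1, cod2)
  Nd <- sum(diffs["nd", ]); Sd <- sum(diffs["sd", ])
  pN <- if (N > 0) Nd / N else 0
  pS <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  ka <- jc(pN); ks <- jc(pS)
  rnd <- function(x) floor(x + 0.5)  # half-up, test only
  tab <- matrix(rnd(c(Nd, N - Nd, Sd, S - Sd)), 2, 2, byrow = TRUE)
  pf <- stats::fisher.test(tab)$p.value
  structure(list(ka = ka, ks = ks,
                 omega = if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks
                         else NA_real_,
                 N = N, S = S, Nd = Nd, Sd = Sd, p_fisher = pf),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %.4f  Ks = %.4f  Ka/Ks = %s  (N = %.1f, S = %.1f, Nd = %.2f, Sd = %.2f, Fisher p = %.3g)\n",
              x$ka, x$ks,
              if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega),
              x$N, x$S, x$Nd, x$Sd, x$p_fisher))
  invisible(x)
}

#' Read a two-sequence codon alignment from FASTA
#'
#' @param path FASTA file with two records, or the first of two
#'   single-record files.
#' @param path2 optional second FASTA file.
#' @return character vector of two sequences, named by record.
#' @export
read_codon_pair <- function(path, path2 = NULL) {
  rd <- function(p) {
    lines <- readLines(p)
    hd <- grep("^>", lines)
    if (!length(hd)) stop("no FASTA records in ", p)
    bounds <- c(hd, length(lines) + 1)
    vapply(seq_along(hd), function(i)
      paste(lines[(bounds[i] + 1):(bounds[i + 1] - 1)], collapse = ""),
      character(1)) |>
      setNames(sub("^>\\s*(\\S+).*", "\\1", lines[hd]))
  }
  seqs <- if (is.null(path2)) rd(path) else c(rd(path), rd(path2))
  if (length(seqs) != 2) stop("exactly two FASTA records required, got ",
                              length(seqs))
  seqs
}

#' Molecular-clock conversion T = K_S / (2 r)
#'
#' Given any two of synonymous divergence `K_S`, yearly synonymous rate `r`
#' and divergence time `T` (years), solves for the third, and reports the
#' per-generation rate for the given generation time.
#'
#' @param ks synonymous substitutions per site (K_S).
#' @param r synonymous substitution rate per site per year.
#' @param t divergence time in years.
#' @param generation_time generation time in years.
#' @return a `divergence_estimate` list with `ks`, `r_per_year`, `t_years`,
#'   `r_per_generation`.
#' @export
clock_convert <- function(ks = NULL, r = NULL, t = NULL,
                          generation_time = 10) {
  given <- !vapply(list(ks, r, t), is.null, logical(1))
  if (sum(given) != 2)
    stop("exactly two of {ks, r, t} must be given")
  vals <- c(ks = if (given[1]) ks else NA,
            r = if (given[2]) r else NA, t = if (given[3]) t else NA)
  if (any(vals < 0, na.rm = TRUE) || (given[2] && r <= 0) ||
      (given[3] && t < 0))
    stop("inputs must be positive (K_S and T may be zero only together)")
  if (!given[1]) ks <- 2 * r * t
  if (!given[2]) {
    if (t <= 0) stop("T must be > 0 to solve for r")
    r <- ks / (2 * t)
  }
  if (!given[3]) t <- ks / (2 * r)
  structure(list(ks = ks, r_per_year = r, t_years = t,
                 r_per_generation = r * generation_time,
                 generation_time = generation_time),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("K_S = %.4g, r = %.4g /site/yr (%.4g /site/gen at %g-y generations), T = %.4g yr\n",
              x$ks, x$r_per_year, x$r_per_generation, x$generation_time,
              x$t_years))
  invisible(x)
}
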