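# Independent brute-force oracles. These deliberately re-derive every
# statistic from first principles (loops over sites/samples/pathways),
# staying independent of the vectorized implementation paths they check.

# --- per-site diversity oracles -------------------------------------------

oracle_site_pi <- function(dosages) {
  # mean pairwise difference per site among the 2N haplotypes implied by
  # dosages, computed from allele frequency with n/(n-1) correction
  x <- dosages[!is.na(dosages)]
  n <- 2 * length(x)
  if (n < 2) return(NA_real_)
  p <- sum(x) / n
  2 * p * (1 - p) * n / (n - 1)
}

oracle_site_dxy <- function(dx, dy) {
  x <- dx[!is.na(dx)]; y <- dy[!is.na(dy)]
  if (!length(x) || !length(y)) return(NA_real_)
  px <- sum(x) / (2 * length(x)); py <- sum(y) / (2 * length(y))
  px * (1 - py) + py * (1 - px)
}

oracle_site_he <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  if (length(x) < 1) return(NA_real_)
  p <- sum(x) / (2 * length(x))
  2 * p * (1 - p)
}

oracle_window_stats <- function(geno, pops, pop_a, pop_b) {
  # geno: sites x samples dosage matrix; returns pi_a, pi_b, dxy, fst
  a <- which(pops == pop_a); b <- which(pops == pop_b)
  pia <- pib <- dxy <- hw <- numeric(0)
  for (s in seq_len(nrow(geno))) {
    ha <- oracle_site_pi(geno[s, a])
    hb <- oracle_site_pi(geno[s, b])
    dd <- oracle_site_dxy(geno[s, a], geno[s, b])
    if (is.na(ha) || is.na(hb) || is.na(dd)) next
    pia <- c(pia, ha); pib <- c(pib, hb); dxy <- c(dxy, dd)
    hw <- c(hw, (oracle_site_he(geno[s, a]) + oracle_site_he(geno[s, b])) / 2)
  }
  list(pi_a = mean(pia), pi_b = mean(pib), dxy = mean(dxy),
       fst = 1 - mean(hw) / mean(dxy))
}

# --- Tajima's D oracle (independent coding of the 1989 constants) ---------

oracle_tajima <- function(n, S, pi_abs) {
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (pi_abs - S / a1) / sqrt(c1 / a1 * S + c2 / (a1 * a1 + a2) * S * (S - 1))
}

# mean pairwise differences among haplotype rows, by explicit enumeration
oracle_pi_abs_haps <- function(haps) {
  n <- nrow(haps); tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ]); np <- np + 1
  }
  tot / np
}

# --- Fu & Li oracle (independent coding of the 1993 constants) ------------

oracle_fu_li_d <- function(n, eta, eta_e) {
  a <- sum(1 / (1:(n - 1))); b <- sum(1 / (1:(n - 1))^2)
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v <- 1 + a^2 / (b + a^2) * (cn - (n + 1) / (n - 1))
  u <- a - 1 - v
  (eta - a * eta_e) / sqrt(u * eta + v * eta^2)
}

oracle_fu_li_f <- function(n, eta, eta_e, pi_abs) {
  a <- sum(1 / (1:(n - 1))); b <- sum(1 / (1:(n - 1))^2)
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) / (a^2 + b)
  u <- (1 + (n + 1) / (3 * (n - 1)) -
          4 * (n + 1) / (n - 1)^2 * (a + 1 / n - 2 * n / (n + 1))) / a - v
  (pi_abs - eta_e) / sqrt(u * eta + v * eta^2)
}

# --- jackknife oracle: explicit delete-one on the weighted mean -----------

oracle_jackknife_mean_se <- function(values) {
  # equal-weight delete-one jackknife SE of the mean
  n <- length(values)
  loo <- sapply(seq_len(n), function(i) mean(values[-i]))
  sqrt((n - 1) / n * sum((loo - mean(loo))^2))
}

# --- f_dM site-level oracle (literal transcription of the rule) -----------

oracle_fdm_site <- function(p1, p2, p3, p4) {
  abba <- function(a, b, c, d) (1 - a) * b * c * (1 - d)
  baba <- function(a, b, c, d) a * (1 - b) * c * (1 - d)
  num <- abba(p1, p2, p3, p4) - baba(p1, p2, p3, p4)
  if (p2 >= p1) {
    pD <- max(p2, p3)
    den <- abba(p1, pD, pD, p4) - baba(p1, pD, pD, p4)
  } else {
    pD <- max(p1, p3)
    den <- -(abba(pD, p2, pD, p4) - baba(pD, p2, pD, p4))
  }
  c(num = num, den = den)
}

# --- NG86 pathway-enumeration oracle --------------------------------------

oracle_codon_table <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_ng86_pair <- function(s1, s2) {
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- codons(s1); c2 <- codons(s2)
  syn_sites <- function(cd) {
    aa <- oracle_codon_table[[cd]]
    s <- 0
    for (i in 1:3) for (nt in setdiff(c("T","C","A","G"), substr(cd, i, i))) {
      alt <- cd; substr(alt, i, i) <- nt
      if (oracle_codon_table[[alt]] == aa && aa != "*") s <- s + 1/3
    }
    s
  }
  all_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  S <- sum(sapply(c1, syn_sites) + sapply(c2, syn_sites)) / 2
  N <- 3 * length(c1) - S
  Nd <- Sd <- 0
  for (k in seq_along(c1)) {
    pos <- which(strsplit(c1[k], "")[[1]] != strsplit(c2[k], "")[[1]])
    if (!length(pos)) next
    counts <- list()
    for (ord in all_perms(pos)) {
      cur <- c1[k]; nd <- sd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2[k], p, p)
        if (oracle_codon_table[[nxt]] == "*" && nxt != c2[k]) blocked <- TRUE
        if (oracle_codon_table[[cur]] == oracle_codon_table[[nxt]] &&
            oracle_codon_table[[cur]] != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      counts[[length(counts) + 1]] <- list(nd = nd, sd = sd, blocked = blocked)
    }
    ok <- Filter(function(x) !x$blocked, counts)
    if (!length(ok)) ok <- counts
    Nd <- Nd + mean(sapply(ok, `[[`, "nd"))
    Sd <- Sd + mean(sapply(ok, `[[`, "sd"))
  }
  list(N = N, S = S, Nd = Nd, Sd = Sd)
}

# --- conjugate-normal evidence by numerical integration -------------------

oracle_evidence_numeric <- function(y, sigma, prior_mean, prior_sd) {
  # integrate likelihood * prior over the mean on a wide grid (log-sum-exp)
  grid <- seq(prior_mean - 12 * prior_sd, prior_mean + 12 * prior_sd,
              length.out = 40001)
  h <- grid[2] - grid[1]
  lp <- sapply(grid, function(mu)
    sum(dnorm(y, mu, sigma, log = TRUE)) + dnorm(mu, prior_mean, prior_sd,
                                                 log = TRUE))
  m <- max(lp)
  m + log(sum(exp(lp - m)) * h)
}

# --- misc ------------------------------------------------------------------

# migration rate between P1 and P2 as a function of time, reconstructed
# from a model's event list (for structural preset checks)
oracle_pair_mig_rate <- function(model, times) {
  mg <- Filter(function(e) e$type == "migration", model$events)
  sapply(times, function(t) {
    rate <- 0
    for (e in mg) if (e$time <= t) rate <- e$rates["P1", "P2"]
    rate
  })
}
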