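# Joint-SFS construction and simulation-based composite-likelihood fitting
# of the four two-population gene-flow models, parameter scaling and a
# pulse-direction test.
#
# The expected SFS under a candidate parameter vector is estimated by Monte
# Carlo from the package's own coalescent engine. Optimization uses
# multi-start Nelder-Mead on log parameters with common random numbers
# (fixed simulation seeds within a start), a derivative-free, reproducible
# stand-in for the cycle-based maximization used with far larger
# simulation budgets on cluster hardware.

#' Unfolded joint site frequency spectrum
#'
#' Accumulates derived-allele counts of a population pair into an
#' `(n1 + 1) x (n2 + 1)` haplotype-count grid. Genotype dosages are taken
#' to count derived alleles (REF = ancestral; use [polarize_by_outgroup()]
#' first for empirical data). With a `projection`, each site with at least
#' the projected number of called alleles in both populations contributes
#' its hypergeometric expectation over the smaller grid; sites below the
#' projection are dropped and counted. The fixed-fixed corners (0,0) and
#' (n1,n2) are masked and excluded from likelihoods.
#'
#' @param gm a `genotype_matrix` with derived-allele dosages.
#' @param pop_pair character vector of two population labels.
#' @param projection optional integer vector of two projected haplotype
#'   counts.
#' @param folded fold the spectrum by minor-allele count (rarely needed;
#'   the fitting path uses unfolded spectra).
#' @param seq_length optional number of accessible (surveyed) sites the
#'   SNPs were ascertained from. When given, [composite_loglik()] adds a
#'   Poisson term on the total SNP count, anchoring the absolute scale of
#'   demographic parameters (otherwise only the normalized spectrum shape
#'   informs the fit and the overall time/size scale is weakly
#'   identified).
#' @return a `joint_sfs`: list with `counts` (matrix), `pops`, `mask`
#'   (logical matrix of masked entries), `total` (usable SNPs),
#'   `n_dropped`, `polarized`, `seq_length`.
#' @export
joint_sfs <- function(gm, pop_pair, projection = NULL, folded = FALSE,
                      seq_length = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), length(pop_pair) == 2)
  f1 <- pop_counts(gm, pop_pair[1])
  f2 <- pop_counts(gm, pop_pair[2])
  n1 <- max(f1$n); n2 <- max(f2$n)
  if (is.null(projection)) {
    use <- f1$n == n1 & f2$n == n2
    m1 <- n1; m2 <- n2
    counts <- matrix(0, m1 + 1, m2 + 1)
    if (any(use)) {
      tab <- table(factor(f1$d[use], levels = 0:m1),
                   factor(f2$d[use], levels = 0:m2))
      counts <- counts + unclass(tab)
    }
    n_dropped <- sum(!use)
  } else {
    m1 <- projection[1]; m2 <- projection[2]
    if (m1 > n1 || m2 > n2)
      stop("projection larger than available haplotype counts (", n1, ", ",
           n2, ")")
    use <- f1$n >= m1 & f2$n >= m2
    n_dropped <- sum(!use)
    counts <- matrix(0, m1 + 1, m2 + 1)
    w1 <- which(use)
    for (s in w1) {
      pr1 <- dhyper(0:m1, f1$d[s], f1$n[s] - f1$d[s], m1)
      pr2 <- dhyper(0:m2, f2$d[s], f2$n[s] - f2$d[s], m2)
      counts <- counts + outer(pr1, pr2)
    }
  }
  dimnames(counts) <- list(0:m1, 0:m2)
  mask <- matrix(FALSE, m1 + 1, m2 + 1)
  mask[1, 1] <- TRUE
  mask[m1 + 1, m2 + 1] <- TRUE
  if (folded) {
    folded_counts <- counts
    for (i in 0:m1) for (j in 0:m2) {
      if (i + j > (m1 + m2) / 2) {
        folded_counts[m1 - i + 1, m2 - j + 1] <-
          folded_counts[m1 - i + 1, m2 - j + 1] + folded_counts[i + 1, j + 1]
        folded_counts[i + 1, j + 1] <- 0
      }
    }
    counts <- folded_counts
  }
  structure(list(counts = counts, pops = pop_pair, mask = mask,
                 total = sum(counts[!mask]), n_dropped = n_dropped,
                 polarized = !folded, seq_length = seq_length),
            class = "joint_sfs")
}

pop_counts <- function(gm, pop) {
  cols <- gm$samples$pop == pop
  if (!any(cols)) stop("no samples in population: ", pop)
  sub <- gm$geno[, cols, drop = FALSE]
  list(d = rowSums(sub, na.rm = TRUE), n = 2 * rowSums(!is.na(sub)))
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs> ", x$pops[1], " x ", x$pops[2], ", grid ",
      nrow(x$counts), "x", ncol(x$counts), ", ", round(x$total, 1),
      " usable SNPs\n", sep = "")
  invisible(x)
}

#' Monte-Carlo expected joint SFS under a demographic model
#'
#' Estimates the expected unfolded joint SFS of the two sampled demes from
#' `n_sims` independent simulated genealogies. The default `"branch"`
#' method accumulates branch lengths by the derived-leaf configuration of
#' each branch — the exact conditional expectation of the infinite-sites
#' spectrum given each genealogy — which removes all mutation-sampling
#' noise (Rao-Blackwellization) and makes desk-scale composite-likelihood
#' surfaces usable. The `"mutation"` method drops Poisson mutations and
#' counts simulated SNPs (kept as the cross-check of the branch method).
#' Fixed corners are masked; a pseudocount floor `eps` on empty entries
#' prevents `log(0)`; the grid is renormalized over unmasked entries.
#'
#' @param model a two-deme-sampled [demographic_model()].
#' @param sampling named diploid sample counts for exactly two demes.
#' @param n_sims number of simulated genealogies (loci).
#' @param locus_length locus length in bp (used by the `"mutation"`
#'   method and for the SNP-rate scale; the branch-method shape is
#'   independent of it).
#' @param seed integer seed.
#' @param method `"branch"` or `"mutation"`.
#' @return list with `probs` (normalized grid), `mask`, `n_snps`
#'   (simulated SNPs, or their expectation under `"branch"`), `snp_rate`
#'   (expected SNPs per surveyed site).
#' @export
expected_sfs <- function(model, sampling, n_sims = 500, locus_length = 2000,
                         seed, method = c("branch", "mutation")) {
  method <- match.arg(method)
  if (length(sampling) != 2) stop("two-deme sampling required")
  if (missing(seed)) stop("an explicit seed is required")
  pops <- names(sampling)
  n1h <- 2 * sampling[[1]]; n2h <- 2 * sampling[[2]]
  if (method == "branch") {
    cpp <- branch_sfs_call(model, sampling, n_sims, seed)
    counts <- cpp$branch_sfs * model$mutation_rate * locus_length
    n_snps <- cpp$mean_total_len * model$mutation_rate * locus_length * n_sims
    snp_rate <- cpp$mean_total_len * model$mutation_rate
  } else {
    sim <- simulate_dataset(model, sampling, n_loci = n_sims,
                            locus_length = locus_length, seed = seed)
    hp <- rep(rep(pops, times = sampling), each = 2)
    d1 <- colSums(sim$hap_geno[hp == pops[1], , drop = FALSE])
    d2 <- colSums(sim$hap_geno[hp == pops[2], , drop = FALSE])
    counts <- unclass(table(factor(d1, levels = 0:n1h),
                            factor(d2, levels = 0:n2h)))
    n_snps <- sum(counts)
    snp_rate <- n_snps / (n_sims * locus_length)
  }
  mask <- matrix(FALSE, n1h + 1, n2h + 1)
  mask[1, 1] <- TRUE; mask[n1h + 1, n2h + 1] <- TRUE
  if (sum(counts[!mask]) <= 0)
    stop("zero usable simulated SNPs; increase n_sims or locus_length")
  probs <- counts
  probs[mask] <- 0
  eps <- 0.5 / max(n_snps, 1)
  probs[!mask & probs == 0] <- eps
  probs <- probs / sum(probs[!mask])
  dimnames(probs) <- list(0:n1h, 0:n2h)
  list(probs = probs, mask = mask, n_snps = n_snps, snp_rate = snp_rate)
}

# marshal a model for the branch-SFS core (two sampled demes only)
branch_sfs_call <- function(model, sampling, n_sims, seed) {
  nm <- model$demes$name
  nd <- length(nm)
  n_hap <- integer(nd)
  n_hap[match(names(sampling), nm)] <- 2L * as.integer(unlist(sampling))
  sp <- Filter(function(e) e$type != "migration", model$events)
  mg <- Filter(function(e) e$type == "migration", model$events)
  ev_time <- vapply(sp, `[[`, numeric(1), "time")
  ev_type <- vapply(sp, function(e) if (e$type == "split") 0L else 1L,
                    integer(1))
  ev_a <- vapply(sp, function(e)
    match(if (e$type == "split") e$child else e$source, nm) - 1L, integer(1))
  ev_b <- vapply(sp, function(e)
    match(if (e$type == "split") e$parent else e$dest, nm) - 1L, integer(1))
  ev_prop <- vapply(sp, function(e) if (e$type == "pulse") e$prop else 0,
                    numeric(1))
  mig_times <- c(0, vapply(mg, `[[`, numeric(1), "time"))
  mig_mats <- c(list(matrix(0, nd, nd)),
                lapply(mg, function(e) {
                  r <- e$rates
                  if (!is.null(rownames(r))) r <- r[nm, nm, drop = FALSE]
                  unname(r)
                }))
  if (length(mig_times) > 1 && mig_times[2] == 0) {
    mig_times <- mig_times[-1]; mig_mats <- mig_mats[-1]
  }
  .sim_branch_sfs_cpp(n_hap, model$demes$ne, ev_time, ev_type, ev_a, ev_b,
                      ev_prop, mig_times, mig_mats,
                      match(names(sampling)[1], nm) - 1L,
                      match(names(sampling)[2], nm) - 1L,
                      as.integer(n_sims), locus_seeds(seed, n_sims))
}

#' Composite log-likelihood of an observed joint SFS
#'
#' `sum(obs * log(prob))` over unmasked entries: the multinomial
#' log-likelihood up to a data-only constant, treating SNPs as independent
#' (a composite likelihood under linkage). When the observation carries a
#' `seq_length` and the probability grid a simulated `snp_rate`, a Poisson
#' log-probability on the total SNP count is added, anchoring absolute
#' parameter scale.
#'
#' @param obs a [joint_sfs()].
#' @param probs probability grid from [expected_sfs()] (or a bare matrix
#'   normalized over the unmasked entries).
#' @return the composite log-likelihood (non-positive).
#' @export
composite_loglik <- function(obs, probs) {
  stopifnot(inherits(obs, "joint_sfs"))
  p <- if (is.list(probs)) probs$probs else probs
  if (!identical(dim(p), dim(obs$counts)))
    stop("SFS and probability grid shapes differ")
  u <- !obs$mask
  ll <- sum(obs$counts[u] * log(p[u]))
  if (!is.null(obs$seq_length) && is.list(probs) &&
      !is.null(probs$snp_rate) && probs$snp_rate > 0)
    ll <- ll + stats::dpois(round(obs$total),
                            probs$snp_rate * obs$seq_length, log = TRUE)
  ll
}

# ---------------------------------------------------------------------------
# Model templates and fitting
# ---------------------------------------------------------------------------

pair_param_names <- function(label) {
  base <- c("ne1", "ne2", "ne_anc", "t_split")
  switch(label,
         pair_IM_constant = c(base, "m"),
         pair_IM_early = c(base, "m", "alpha"),
         pair_IM_recent = c(base, "m", "alpha"),
         pair_IM_different = c(base, "m_recent", "m_old", "alpha"),
         stop("unknown pair model label: ", label))
}

# default fitting bounds; Ne bounds are the haploid 1000-60000 sampling
# range expressed as diploids, migration 1e-5..1e-2 per generation
pair_param_bounds <- function(label) {
  nm <- pair_param_names(label)
  lo <- c(ne1 = 500, ne2 = 500, ne_anc = 500, t_split = 100,
          m = 1e-5, m_recent = 1e-5, m_old = 1e-5, alpha = 0.05)
  hi <- c(ne1 = 30000, ne2 = 30000, ne_anc = 30000, t_split = 1e5,
          m = 0.01, m_recent = 0.01, m_old = 0.01, alpha = 0.95)
  cbind(lower = lo[nm], upper = hi[nm])
}

pair_model_from_params <- function(label, par) {
  par <- as.list(par)
  alpha <- if (!is.null(par$alpha)) par$alpha else 0.5
  args <- list(name = label, ne1 = par$ne1, ne2 = par$ne2,
               ne_anc = par$ne_anc, t_split = par$t_split,
               boundary = alpha * par$t_split)
  if (label == "pair_IM_different") {
    args$m_recent <- par$m_recent; args$m_old <- par$m_old
  } else args$m <- par$m
  do.call(scenario_preset, args)
}

#' Fit a two-population gene-flow model to an observed joint SFS
#'
#' Multi-start Nelder-Mead maximization of the composite log-likelihood
#' over log-transformed parameters (logit for the epoch-boundary fraction
#' `alpha`), with common random numbers: within each start, every
#' likelihood evaluation reuses the same simulation seed, so the objective
#' is a deterministic function of the parameters.
#'
#' @param obs a [joint_sfs()] (unfolded).
#' @param model_template one of `"pair_IM_constant"`, `"pair_IM_early"`,
#'   `"pair_IM_recent"`, `"pair_IM_different"`.
#' @param sampling named diploid counts for the two demes `P1`, `P2`
#'   (sizes must match the observed grid).
#' @param bounds optional 2-column matrix (lower, upper) over the model's
#'   parameters, defaulting to the declared sampling ranges.
#' @param n_starts independent optimizer starts.
#' @param max_iters Nelder-Mead iterations per start.
#' @param sims_per_eval simulated genealogies per likelihood evaluation.
#' @param refine_factor multiplier on `sims_per_eval` for the final
#'   polishing restart.
#' @param profile_ridge when split time and a single migration rate are
#'   both free, finish with a common-stream profile grid over the
#'   (t_split, m) ridge at a large batch size (5 x the polish batch).
#' @param locus_length simulated locus length (bp).
#' @param seed integer seed governing starts and simulation streams.
#' @param fixed named list of parameters to hold fixed (excluded from
#'   optimization).
#' @return a `fit_result`: list with `label`, `par` (natural scale),
#'   `loglik`, `trace` (per-start best values), `seed`, `obs_total`.
#' @export
fit_model <- function(obs, model_template, sampling, bounds = NULL,
                      n_starts = 3, max_iters = 40, sims_per_eval = 2000,
                      refine_factor = 4, profile_ridge = TRUE,
                      locus_length = 2000, seed, fixed = list()) {
  stopifnot(inherits(obs, "joint_sfs"))
  if (missing(seed)) stop("an explicit seed is required")
  nm <- pair_param_names(model_template)
  bd <- if (is.null(bounds)) pair_param_bounds(model_template) else bounds
  free <- setdiff(nm, names(fixed))
  if (!length(free)) { # degenerate: everything fixed -> direct evaluation
    par <- unlist(fixed)[nm]
    es <- expected_sfs(pair_model_from_params(model_template, par), sampling,
                       n_sims = sims_per_eval, locus_length = locus_length,
                       seed = seed)
    return(structure(list(label = model_template, par = par,
                          loglik = composite_loglik(obs, es),
                          trace = data.frame(start = 1L,
                                             loglik = composite_loglik(obs, es)),
                          seed = seed, obs_total = obs$total),
                     class = "fit_result"))
  }
  is_alpha <- free == "alpha"
  to_internal <- function(p) ifelse(is_alpha, log(p / (1 - p)), log(p))
  to_natural <- function(x) ifelse(is_alpha, 1 / (1 + exp(-x)), exp(x))

  lo <- bd[free, "lower"]; hi <- bd[free, "upper"]
  objective <- function(x, sim_seed, n_sims = sims_per_eval) {
    p <- to_natural(x)
    if (any(p < lo) || any(p > hi)) return(1e12)
    par <- setNames(numeric(length(nm)), nm)
    par[free] <- p
    if (length(fixed)) par[names(fixed)] <- unlist(fixed)
    es <- tryCatch(
      expected_sfs(pair_model_from_params(model_template, par), sampling,
                   n_sims = n_sims, locus_length = locus_length,
                   seed = sim_seed),
      error = function(e) NULL)
    if (is.null(es)) return(1e12)
    -composite_loglik(obs, es)
  }

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647)
  # random log-uniform pre-screen; Nelder-Mead launches from the best
  # screened points (the surface is mildly jagged under Monte-Carlo
  # evaluation, so good starting regions matter more than long runs)
  n_screen <- max(20, 6 * n_starts)
  screen_seed <- (seed * 131) %% 2147483647
  cand <- replicate(n_screen,
                    exp(log(lo) + runif(length(free)) * (log(hi) - log(lo))),
                    simplify = FALSE)
  sv <- vapply(cand, function(p) objective(to_internal(p), screen_seed),
               numeric(1))
  # starts stratified over split time when it is free: the composite
  # surface has a known ridge (old split + strong migration mimics recent
  # split + weak migration), so random starts alone can all fall into one
  # basin; taking the best screened candidate within each log-band of
  # t_split guarantees both basins are explored
  if ("t_split" %in% free && n_starts > 1) {
    ti <- match("t_split", free)
    tvals <- vapply(cand, `[`, numeric(1), ti)
    bands <- cut(log(tvals),
                 breaks = seq(log(lo[ti]), log(hi[ti]),
                              length.out = n_starts + 1),
                 include.lowest = TRUE)
    starts <- lapply(split(seq_along(cand), bands), function(ix) {
      if (!length(ix)) return(NULL)
      cand[[ix[which.min(sv[ix])]]]
    })
    starts <- Filter(Negate(is.null), starts)
  } else {
    ord <- order(sv)
    starts <- cand[ord[seq_len(min(n_starts, sum(is.finite(sv))))]]
  }
  endpoints <- list()
  trace <- data.frame(start = integer(0), loglik = numeric(0))
  for (i in seq_along(starts)) {
    sim_seed <- (seed * 131 + i * 7919) %% 2147483647
    fit <- tryCatch(
      optim(to_internal(starts[[i]]), objective, sim_seed = sim_seed,
            method = "Nelder-Mead",
            control = list(maxit = max_iters, reltol = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e12) next
    trace <- rbind(trace, data.frame(start = i, loglik = -fit$value))
    endpoints[[length(endpoints) + 1]] <- fit$par
  }
  if (!length(endpoints))
    stop("optimizer failed on all starts; check bounds and sims_per_eval")
  # basin comparison and polish at refine_factor times the batch size on a
  # single common stream: per-start common-random-number optima overfit
  # their own stream by roughly the evaluation noise, and distinct starts
  # can end in distinct ridge basins (old-split/high-migration versus the
  # truth-like basin), so endpoints must be compared on one low-noise
  # stream before the final refinement
  refine_seed <- (seed * 131 + 999983) %% 2147483647
  refine_ns <- refine_factor * sims_per_eval
  cand_vals <- vapply(endpoints, function(x)
    objective(x, refine_seed, refine_ns), numeric(1))
  keep <- order(cand_vals)[seq_len(min(2, length(endpoints)))]
  best <- list(par = endpoints[[keep[1]]], value = cand_vals[keep[1]],
               sim_seed = refine_seed)
  for (k in keep) {
    fit2 <- tryCatch(
      optim(endpoints[[k]], objective, sim_seed = refine_seed,
            n_sims = refine_ns, method = "Nelder-Mead",
            control = list(maxit = max_iters, reltol = 1e-7)),
      error = function(e) NULL)
    if (!is.null(fit2) && is.finite(fit2$value) && fit2$value < best$value) {
      fit2$sim_seed <- refine_seed
      best <- fit2
    }
  }
  # ridge-profile grid: split time and migration rate trade off along a
  # shallow likelihood ridge whose curvature (a few log-units per 25% of
  # split time) sits below the Monte-Carlo noise of the polishing batches,
  # so the last word on (t_split, m) is a common-stream grid evaluation at
  # a much larger batch size, centered on the polished optimum
  if (all(c("t_split", "m") %in% free) && profile_ridge) {
    it <- match("t_split", free); im <- match("m", free)
    cur <- to_natural(best$par)
    ts <- cur[it] * 2^seq(-0.8, 0.8, length.out = 9)
    ms <- cur[im] * 2^seq(-1, 1, length.out = 7)
    ts <- pmin(pmax(ts, lo[it]), hi[it])
    ms <- pmin(pmax(ms, lo[im]), hi[im])
    grid_ns <- 5 * refine_ns
    gbest <- best$value
    for (tv in ts) for (mv in ms) {
      x <- best$par
      x[it] <- log(tv); x[im] <- log(mv)
      v <- objective(x, refine_seed, grid_ns)
      if (v < gbest) { gbest <- v; best$par <- x; best$value <- v }
    }
  }
  par <- setNames(numeric(length(nm)), nm)
  par[free] <- to_natural(best$par)
  if (length(fixed)) par[names(fixed)] <- unlist(fixed)
  structure(list(label = model_template, par = par, loglik = -best$value,
                 trace = trace, seed = seed, sim_seed = best$sim_seed,
                 obs_total = obs$total),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$label, "  CL = ", sprintf("%.2f", x$loglik), "\n",
      sep = "")
  print(signif(x$par, 4))
  invisible(x)
}

#' Rank fitted gene-flow models
#'
#' Ranks fits of the same observed SFS by maximum composite likelihood or
#' AIC (`-2 CL + 2 k`, k = number of parameters).
#'
#' @param fits list of [fit_model()] results on the same observation.
#' @param criterion `"maxCL"` or `"AIC"`.
#' @return data.frame ranked best-first with `label`, `loglik`, `k`,
#'   `aic`, `delta` (vs best).
#' @export
model_select <- function(fits, criterion = c("maxCL", "AIC")) {
  criterion <- match.arg(criterion)
  if (length(fits) < 2) stop("at least two fits required")
  tot <- vapply(fits, `[[`, numeric(1), "obs_total")
  if (length(unique(round(tot, 6))) != 1)
    stop("fits were computed on different observed SFS")
  k <- vapply(fits, function(f) length(pair_param_names(f$label)), numeric(1))
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  aic <- -2 * ll + 2 * k
  ord <- if (criterion == "maxCL") order(-ll) else order(aic)
  out <- data.frame(label = vapply(fits, `[[`, "", "label"),
                    loglik = ll, k = k, aic = aic)[ord, ]
  out$delta <- if (criterion == "maxCL") max(ll) - out$loglik
               else out$aic - min(out$aic)
  rownames(out) <- NULL
  out
}

#' Test the direction of an admixture pulse
#'
#' Adds a single pulse to `base_model` in each direction (P1 -> P2 and
#' P2 -> P1), fits the pulse parameters (proportion phi and pulse time) to
#' the observed joint SFS by composite likelihood while holding the base
#' demography fixed, and reports the likelihood difference. Optionally,
#' thermodynamic integration (via [log_marginal_ti()]) turns each
#' direction into a marginal likelihood and a Bayes factor.
#'
#' @param obs a [joint_sfs()] of the two populations (P1 = first, P2 =
#'   second grid axis).
#' @param base_model a two-deme [demographic_model()] with demes `P1`,
#'   `P2` (no pulse).
#' @param sampling named diploid counts matching `obs`.
#' @param pulse_time_bounds bounds for the pulse time (generations);
#'   defaults to (1, split time).
#' @param phi_bounds bounds for phi.
#' @param sims_per_eval,max_iters,n_starts optimizer settings per
#'   direction (see [fit_model()]).
#' @param seed integer seed.
#' @param bayes if `TRUE`, also compute a thermodynamic-integration Bayes
#'   factor between the two directions with the supplied priors.
#' @param ti_settings list of settings passed to the TI run (K, n_burn,
#'   n_samples, thin).
#' @return a `direction_result`: list with `fit_12`, `fit_21`, `delta_cl`
#'   (CL(P1->P2) - CL(P2->P1)), `direction` ("P1->P2", "P2->P1" or
#'   "undetermined"), and optionally `bayes` (a [bayes_factor()] result).
#' @export
direction_test <- function(obs, base_model, sampling,
                           pulse_time_bounds = NULL, phi_bounds = c(0.001, 0.9),
                           sims_per_eval = 400, max_iters = 30, n_starts = 2,
                           seed, bayes = FALSE,
                           ti_settings = list(K = 8, n_burn = 200,
                                              n_samples = 400, thin = 2)) {
  stopifnot(inherits(obs, "joint_sfs"), inherits(base_model, "demographic_model"))
  if (missing(seed)) stop("an explicit seed is required")
  split_t <- min(vapply(Filter(function(e) e$type == "split",
                               base_model$events), `[[`, numeric(1), "time"))
  if (is.null(pulse_time_bounds)) pulse_time_bounds <- c(1, split_t * 0.99)

  fit_dir <- function(src, dst, dseed) {
    lo <- c(phi = phi_bounds[1], t_pulse = pulse_time_bounds[1])
    hi <- c(phi = phi_bounds[2], t_pulse = pulse_time_bounds[2])
    obj <- function(x, sim_seed) {
      p <- exp(x)
      if (any(p < lo) || any(p > hi)) return(1e12)
      m <- add_pulse(base_model, p[["t_pulse"]], src, dst, p[["phi"]])
      es <- tryCatch(expected_sfs(m, sampling, n_sims = sims_per_eval,
                                  seed = sim_seed),
                     error = function(e) NULL)
      if (is.null(es)) return(1e12)
      -composite_loglik(obs, es)
    }
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(dseed %% 2147483647)
    best <- NULL
    for (i in seq_len(n_starts)) {
      x0 <- log(lo) + runif(2) * (log(hi) - log(lo))
      sim_seed <- (dseed * 131 + i * 7919) %% 2147483647
      f <- optim(x0, obj, sim_seed = sim_seed, method = "Nelder-Mead",
                 control = list(maxit = max_iters, reltol = 1e-6))
      if (is.null(best) || f$value < best$value) best <- f
    }
    list(par = setNames(exp(best$par), c("phi", "t_pulse")),
         loglik = -best$value)
  }

  fit_12 <- fit_dir("P1", "P2", seed)
  fit_21 <- fit_dir("P2", "P1", seed + 1)
  delta <- fit_12$loglik - fit_21$loglik
  res <- list(fit_12 = fit_12, fit_21 = fit_21, delta_cl = delta,
              direction = if (delta > 0) "P1->P2"
                          else if (delta < 0) "P2->P1" else "undetermined")
  if (bayes) {
    mk_model <- function(src, dst) {
      ti_model(
        log_prior = function(th) {
          stats::dbeta(th[1], 6, 200, log = TRUE) +
            stats::dunif(th[2], pulse_time_bounds[1], pulse_time_bounds[2],
                         log = TRUE)
        },
        sample_prior = function() c(stats::rbeta(1, 6, 200),
                                    stats::runif(1, pulse_time_bounds[1],
                                                 pulse_time_bounds[2])),
        log_lik = function(th) {
          m <- add_pulse(base_model, th[2], src, dst, min(th[1], 1))
          es <- tryCatch(expected_sfs(m, sampling, n_sims = sims_per_eval,
                                      seed = (seed * 977) %% 2147483647),
                         error = function(e) NULL)
          if (is.null(es)) return(-1e12)
          composite_loglik(obs, es)
        },
        dim = 2, lower = c(0, pulse_time_bounds[1]),
        upper = c(1, pulse_time_bounds[2]),
        prop_scale = c(0.02, diff(pulse_time_bounds) / 20))
    }
    sched <- power_schedule(ti_settings$K)
    m1 <- log_marginal_ti(mk_model("P1", "P2"), sched,
                          n_burn = ti_settings$n_burn,
                          n_samples = ti_settings$n_samples,
                          thin = ti_settings$thin, seed = seed + 11)
    m0 <- log_marginal_ti(mk_model("P2", "P1"), sched,
                          n_burn = ti_settings$n_burn,
                          n_samples = ti_settings$n_samples,
                          thin = ti_settings$thin, seed = seed + 13)
    res$bayes <- bayes_factor(m1$log_marginal, m0$log_marginal)
    res$m1 <- m1; res$m0 <- m0
  }
  class(res) <- "direction_result"
  res
}

#' @export
print.direction_result <- function(x, ...) {
  cat(sprintf("direction test: CL(P1->P2) = %.2f, CL(P2->P1) = %.2f, delta = %.2f -> %s\n",
              x$fit_12$loglik, x$fit_21$loglik, x$delta_cl, x$direction))
  invisible(x)
}

# insert a pulse event into a model, keeping events time-sorted
add_pulse <- function(model, time, source, dest, prop) {
  ev <- c(model$events, list(ev_pulse(time, source, dest, prop)))
  ev <- ev[order(vapply(ev, `[[`, numeric(1), "time"))]
  demographic_model(model$demes, ev, model$mutation_rate,
                    model$generation_time)
}

#' Scale fitted parameters to absolute units
#'
#' Converts event times from generations to years using the generation
#' time, optionally recalibrating linearly so that a named event (e.g. the
#' species split) matches a known absolute age (6.4 My for the system's
#' species split).
#'
#' @param fit a [fit_model()] result (or any named vector with `t_split`).
#' @param mutation_rate per-site per-generation mutation rate.
#' @param generation_time generation time in years.
#' @param calibrate optional list `list(param = "t_split", age_years = x)`
#'   forcing the named time parameter to the given absolute age and
#'   scaling all other time parameters by the same factor.
#' @return data.frame with columns `param`, `value`, `unit`.
#' @export
scale_params <- function(fit, mutation_rate = 6.675e-8, generation_time = 10,
                         calibrate = NULL) {
  if (mutation_rate <= 0 || generation_time <= 0)
    stop("scaling constants must be positive")
  par <- if (inherits(fit, "fit_result")) fit$par else unlist(fit)
  is_time <- grepl("^t_", names(par))
  years <- par
  years[is_time] <- par[is_time] * generation_time
  cal <- 1
  if (!is.null(calibrate)) {
    if (!calibrate$param %in% names(par)[is_time])
      stop("calibration node not among time parameters: ", calibrate$param)
    cal <- calibrate$age_years / years[[calibrate$param]]
    years[is_time] <- years[is_time] * cal
  }
  unit <- ifelse(is_time, "years",
                 ifelse(grepl("^ne", names(par)), "diploids",
                        ifelse(grepl("^m", names(par)), "per generation", "")))
  data.frame(param = names(par), value = as.numeric(years), unit = unit,
             generations = as.numeric(ifelse(is_time, par, NA)),
             calibration_factor = cal, stringsAsFactors = FALSE)
}
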