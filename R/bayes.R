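# Power-posterior sampling and thermodynamic-integration marginal
# likelihoods with Gauss-Legendre quadrature; Bayes-factor support calls.
#
# The estimator is implemented literally as M = sum_k w_k * E_k / 2 with
# the original Gauss-Legendre weights on (-1, 1): the division by 2 is the
# interval change from (-1, 1) to beta in (0, 1).

#' Build a model interface for the sampler
#'
#' A minimal interface consumed by [mh_sample()] and [log_marginal_ti()]:
#' log prior and log likelihood evaluators, a prior sampler, the parameter
#' dimension with box bounds, and componentwise proposal scales.
#'
#' @param log_prior function(theta) returning the log prior density.
#' @param sample_prior function() returning one draw from the prior.
#' @param log_lik function(theta) returning the log likelihood.
#' @param dim parameter dimension.
#' @param lower,upper box bounds (priors must integrate to 1 over them).
#' @param prop_scale componentwise random-walk proposal standard
#'   deviations (starting values; adapted during burn-in only).
#' @return a `ti_model` list.
#' @export
ti_model <- function(log_prior, sample_prior, log_lik, dim,
                     lower = rep(-Inf, dim), upper = rep(Inf, dim),
                     prop_scale = rep(1, dim)) {
  structure(list(log_prior = log_prior, sample_prior = sample_prior,
                 log_lik = log_lik, dim = dim, lower = lower, upper = upper,
                 prop_scale = prop_scale),
            class = "ti_model")
}

#' Conjugate normal built-in model (sampler validation)
#'
#' Normal observations with known standard deviation `sigma` and a normal
#' prior on the mean: the marginal likelihood is available in closed form
#' ([evidence_conjugate_normal()]), making this the standard validation
#' target for the thermodynamic-integration machinery.
#'
#' @param y observations.
#' @param sigma known observation standard deviation.
#' @param prior_mean,prior_sd normal prior on the mean.
#' @return a [ti_model()].
#' @export
model_conjugate_normal <- function(y, sigma = 1, prior_mean = 0,
                                   prior_sd = 1) {
  ti_model(
    log_prior = function(th) stats::dnorm(th, prior_mean, prior_sd, log = TRUE),
    sample_prior = function() stats::rnorm(1, prior_mean, prior_sd),
    log_lik = function(th) sum(stats::dnorm(y, th, sigma, log = TRUE)),
    dim = 1, lower = -Inf, upper = Inf,
    prop_scale = max(prior_sd / 2, sigma / sqrt(length(y))))
}

#' Closed-form evidence of the conjugate normal model
#'
#' @inheritParams model_conjugate_normal
#' @return the log marginal likelihood of `y`.
#' @export
evidence_conjugate_normal <- function(y, sigma = 1, prior_mean = 0,
                                      prior_sd = 1) {
  n <- length(y)
  prec_n <- 1 / prior_sd^2 + n / sigma^2
  mean_n <- (prior_mean / prior_sd^2 + sum(y) / sigma^2) / prec_n
  -n / 2 * log(2 * pi * sigma^2) - 0.5 * log(prior_sd^2 * prec_n) -
    sum(y^2) / (2 * sigma^2) - prior_mean^2 / (2 * prior_sd^2) +
    mean_n^2 * prec_n / 2
}

#' Gamma and beta prior constructors
#'
#' Convenience builders for the prior families used in direction-of-flow
#' model choice: divergence times `tau ~ gamma(1, 10)`, mutation-scaled
#' sizes `theta ~ gamma(2, 76)` and introgression probabilities
#' `phi ~ beta(6, 200)` are the conventional choices.
#'
#' @param shape,rate gamma parameters (rate parameterization).
#' @param a,b beta parameters.
#' @return list with `log_d` (log density) and `sample` functions.
#' @export
prior_gamma <- function(shape, rate)
  list(log_d = function(x) stats::dgamma(x, shape, rate, log = TRUE),
       sample = function() stats::rgamma(1, shape, rate))

#' @rdname prior_gamma
#' @export
prior_beta <- function(a, b)
  list(log_d = function(x) stats::dbeta(x, a, b, log = TRUE),
       sample = function() stats::rbeta(1, a, b))

#' Gauss-Legendre power-posterior schedule
#'
#' Places K Gauss-Legendre nodes x_k on (-1, 1), maps them to inverse
#' temperatures `beta_k = (x_k + 1) / 2` in (0, 1) and keeps the original
#' weights (which sum to 2); the `/2` in the TI estimator performs the
#' change of interval. K = 16 is the conventional default.
#'
#' @param K number of quadrature points (>= 2).
#' @return a `power_schedule`: data.frame with `beta` (increasing) and
#'   `weight`.
#' @export
power_schedule <- function(K = 16) {
  if (K < 2) stop("K must be at least 2")
  gl <- pracma::gaussLegendre(K, -1, 1)
  ord <- order(gl$x)
  structure(data.frame(beta = (gl$x[ord] + 1) / 2, weight = gl$w[ord]),
            class = c("power_schedule", "data.frame"))
}

#' Metropolis-Hastings sampling from a power posterior
#'
#' Componentwise Gaussian random-walk MH targeting
#' `prior(theta) * likelihood(theta)^beta`; at `beta = 0` the chain
#' targets the prior. Proposal scales adapt towards ~30% acceptance during
#' burn-in only and are frozen afterwards (preserving detailed balance for
#' the recorded samples).
#'
#' @param model a [ti_model()].
#' @param beta inverse temperature in \[0, 1\].
#' @param n_burn burn-in iterations.
#' @param n_samples recorded samples.
#' @param thin record one sample every `thin` iterations.
#' @param seed integer seed.
#' @return list with `samples` (matrix), `loglik` (per recorded sample),
#'   `mean_loglik`, `se_loglik` (autocorrelation-adjusted MC standard
#'   error), `acceptance`, `ess`.
#' @export
mh_sample <- function(model, beta, n_burn = 10000, n_samples = 1000,
                      thin = 15, seed) {
  stopifnot(inherits(model, "ti_model"), beta >= 0, beta <= 1)
  if (missing(seed)) stop("an explicit seed is required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647)
  d <- model$dim
  scale <- rep(model$prop_scale, length.out = d)
  th <- model$sample_prior()
  lp <- model$log_prior(th); ll <- model$log_lik(th)
  tries <- 0
  while (!is.finite(lp + beta * ll) && tries < 50) {
    th <- model$sample_prior()
    lp <- model$log_prior(th); ll <- model$log_lik(th)
    tries <- tries + 1
  }
  if (!is.finite(lp + beta * ll))
    stop("could not initialize chain at finite density")

  acc <- 0; tot <- 0; acc_win <- 0; tot_win <- 0
  n_iter <- n_burn + n_samples * thin
  samples <- matrix(NA_real_, n_samples, d)
  logliks <- numeric(n_samples)
  rec <- 0
  for (it in seq_len(n_iter)) {
    for (j in seq_len(d)) {
      prop <- th
      prop[j] <- prop[j] + rnorm(1, 0, scale[j])
      lp2 <- model$log_prior(prop)
      if (is.finite(lp2)) {
        ll2 <- model$log_lik(prop)
        lr <- (lp2 + beta * ll2) - (lp + beta * ll)
        if (is.finite(lr) && log(runif(1)) < lr) {
          th <- prop; lp <- lp2; ll <- ll2
          acc <- acc + 1; acc_win <- acc_win + 1
        }
      }
      tot <- tot + 1; tot_win <- tot_win + 1
    }
    if (it <= n_burn && it %% 50 == 0) {
      rate <- acc_win / max(tot_win, 1)
      scale <- scale * exp(rate - 0.3)
      acc_win <- 0; tot_win <- 0
      if (it == n_burn && acc == 0)
        stop("zero acceptance over burn-in; rescale proposals")
    }
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      rec <- rec + 1
      samples[rec, ] <- th
      logliks[rec] <- ll
    }
  }
  ess <- ess_acf(logliks)
  list(samples = samples, loglik = logliks,
       mean_loglik = mean(logliks),
       se_loglik = stats::sd(logliks) / sqrt(max(ess, 1)),
       acceptance = acc / tot, ess = ess)
}

# effective sample size via initial-positive-sequence truncated ACF
ess_acf <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(n)
  a <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in a) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Thermodynamic-integration log marginal likelihood
#'
#' Runs [mh_sample()] at every inverse temperature of the schedule and
#' combines the per-beta mean log-likelihoods E_k as
#' `M = sum_k w_k * E_k / 2` (Gauss-Legendre weights on (-1, 1); the /2 is
#' the interval change). The MC standard error is propagated as
#' `sqrt(sum (w_k/2)^2 se_k^2)`, treating chains as independent across
#' beta (conservative within-chain adjustment via autocorrelation).
#'
#' @param model a [ti_model()].
#' @param schedule a [power_schedule()].
#' @param n_burn,n_samples,thin MCMC settings per beta (see
#'   [mh_sample()]).
#' @param seed integer seed; per-beta seeds are derived from it.
#' @return a `marginal_likelihood` list with `log_marginal`, `se`,
#'   `per_beta` (beta, weight, mean_loglik, se, acceptance, ess).
#' @export
log_marginal_ti <- function(model, schedule = power_schedule(16),
                            n_burn = 10000, n_samples = 1000, thin = 15,
                            seed) {
  stopifnot(inherits(schedule, "power_schedule"))
  if (missing(seed)) stop("an explicit seed is required")
  rows <- lapply(seq_len(nrow(schedule)), function(k) {
    ch <- tryCatch(
      mh_sample(model, schedule$beta[k], n_burn = n_burn,
                n_samples = n_samples, thin = thin,
                seed = (seed * 613 + k * 257) %% 2147483647),
      error = function(e) stop("mh_sample failed at beta = ",
                               signif(schedule$beta[k], 4), ": ",
                               conditionMessage(e)))
    data.frame(beta = schedule$beta[k], weight = schedule$weight[k],
               mean_loglik = ch$mean_loglik, se = ch$se_loglik,
               acceptance = ch$acceptance, ess = ch$ess)
  })
  tab <- do.call(rbind, rows)
  M <- sum(tab$weight * tab$mean_loglik / 2)
  se <- sqrt(sum((tab$weight / 2)^2 * tab$se^2))
  # E[log lik] should be non-decreasing in beta; violations beyond MC
  # error are flagged, not failed
  mono_viol <- any(diff(tab$mean_loglik) < -3 * sqrt(tab$se[-1]^2 +
                                                       tab$se[-nrow(tab)]^2))
  structure(list(log_marginal = M, se = se, per_beta = tab,
                 monotonicity_flag = mono_viol),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat(sprintf("log marginal likelihood M = %.4f (MC SE %.4f, %d beta points)\n",
              x$log_marginal, x$se, nrow(x$per_beta)))
  if (x$monotonicity_flag)
    cat("note: mean log-likelihood not monotone in beta beyond MC error\n")
  invisible(x)
}

#' Bayes factor and support call
#'
#' `B = exp(M1 - M0)` from two log marginal likelihoods, with the decisive
#' support convention: "model 1" when `B > cutoff`, "model 0" when
#' `B < 1/cutoff`, otherwise "undetermined" (default cutoff 100).
#'
#' @param m1,m0 log marginal likelihoods of models 1 and 0.
#' @param cutoff decisive-support cutoff on B.
#' @return a `bayes_factor_result`: list with `b`, `log_b`, `m1`, `m0`,
#'   `call`.
#' @export
bayes_factor <- function(m1, m0, cutoff = 100) {
  if (inherits(m1, "marginal_likelihood")) m1 <- m1$log_marginal
  if (inherits(m0, "marginal_likelihood")) m0 <- m0$log_marginal
  if (!is.finite(m1) || !is.finite(m0)) stop("non-finite log marginal likelihood")
  logb <- m1 - m0
  b <- exp(logb)
  structure(list(b = b, log_b = logb, m1 = m1, m0 = m0,
                 call = if (logb > log(cutoff)) "model 1"
                        else if (logb < -log(cutoff)) "model 0"
                        else "undetermined"),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("B = %.3g (M1 = %.2f, M0 = %.2f) -> %s\n",
              x$b, x$m1, x$m0, x$call))
  invisible(x)
}
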