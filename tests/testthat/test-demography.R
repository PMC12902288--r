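# Joint SFS construction, expected spectra, composite likelihood, fitting
# scaffolding and parameter scaling. The heavier recovery and direction
# experiments live in the acceptance suite.

test_that("joint SFS accumulates counts and masks fixed corners", {
  # 1 SNP with derived counts (1, 0) in pops of 2+2 diploids
  g <- matrix(c(1L, 0L, 0L, 0L), 1)
  gm <- make_gm(g, c("A", "A", "B", "B"))
  sfs <- joint_sfs(gm, c("A", "B"))
  expect_equal(sfs$total, 1)
  expect_equal(sfs$counts["1", "0"], 1)
  expect_true(sfs$mask[1, 1])
  expect_true(sfs$mask[5, 5])
  # monomorphic input -> all-zero spectrum
  g0 <- matrix(0L, 2, 4)
  expect_equal(joint_sfs(make_gm(g0, c("A", "A", "B", "B")),
                         c("A", "B"))$total, 0)
})

test_that("hypergeometric projection matches the expectation oracle", {
  set.seed(21)
  g <- matrix(sample(0:2, 30 * 8, replace = TRUE), 30, 8)
  g[sample(length(g), 12)] <- NA
  pops <- rep(c("A", "B"), each = 4)
  gm <- make_gm(g, pops)
  sfs <- joint_sfs(gm, c("A", "B"), projection = c(4, 4))
  # brute-force oracle: outer product of hypergeometric pmfs per site
  grid <- matrix(0, 5, 5)
  n_used <- 0
  for (s in 1:30) {
    da <- sum(g[s, 1:4], na.rm = TRUE); na <- 2 * sum(!is.na(g[s, 1:4]))
    db <- sum(g[s, 5:8], na.rm = TRUE); nb <- 2 * sum(!is.na(g[s, 5:8]))
    if (na < 4 || nb < 4) next
    n_used <- n_used + 1
    pa <- sapply(0:4, function(j)
      choose(da, j) * choose(na - da, 4 - j) / choose(na, 4))
    pb <- sapply(0:4, function(j)
      choose(db, j) * choose(nb - db, 4 - j) / choose(nb, 4))
    grid <- grid + outer(pa, pb)
  }
  expect_equal(unname(sfs$counts), grid, tolerance = 1e-12)
  expect_equal(sfs$n_dropped, 30 - n_used)
  expect_error(joint_sfs(gm, c("A", "B"), projection = c(10, 4)),
               "projection larger")
})

test_that("expected SFS is symmetric, normalized and deterministic", {
  m <- scenario_preset("pair_IM_constant", ne1 = 4000, ne2 = 4000,
                       ne_anc = 4000, t_split = 3000, m = 1e-4)
  es <- expected_sfs(m, c(P1 = 4, P2 = 4), n_sims = 3000, seed = 9)
  expect_equal(sum(es$probs[!es$mask]), 1, tolerance = 1e-12)
  # symmetric model -> grid symmetric under population swap (MC tolerance)
  asym <- max(abs(es$probs - t(es$probs)))
  expect_lt(asym, 0.01)
  es2 <- expected_sfs(m, c(P1 = 4, P2 = 4), n_sims = 3000, seed = 9)
  expect_identical(es$probs, es2$probs)
  # branch and mutation methods agree
  esm <- expected_sfs(m, c(P1 = 4, P2 = 4), n_sims = 4000, seed = 10,
                      method = "mutation", locus_length = 5000)
  expect_lt(max(abs(es$probs - esm$probs)), 0.01)
})

test_that("a single panmictic deme reproduces the 1/k spectrum", {
  m <- scenario_preset("pair_IM_constant", ne1 = 5000, ne2 = 5000,
                       ne_anc = 5000, t_split = 0.001, m = 1e-5)
  es <- expected_sfs(m, c(P1 = 3, P2 = 3), n_sims = 4000, seed = 33)
  # pooled marginal spectrum of n = 12 haplotypes ~ 1/k
  pooled <- sapply(1:11, function(k) {
    idx <- which(outer(0:6, 0:6, "+") == k, arr.ind = TRUE)
    sum(es$probs[idx])
  })
  expected <- (1 / 1:11) / sum(1 / 1:11)
  expect_lt(max(abs(pooled - expected)), 0.02)
})

test_that("composite log-likelihood equals the brute-force sum", {
  counts <- matrix(c(0, 5, 3, 2, 7, 1, 4, 2, 0), 3)
  obs <- structure(list(counts = counts,
                        mask = matrix(c(TRUE, rep(FALSE, 7), TRUE), 3),
                        total = sum(counts) - counts[1, 1] - counts[3, 3],
                        pops = c("A", "B"), seq_length = NULL),
                   class = "joint_sfs")
  probs <- matrix(runif(9), 3)
  probs[c(1, 9)] <- 0
  probs <- probs / sum(probs)
  brute <- 0
  for (i in 1:3) for (j in 1:3)
    if (!obs$mask[i, j]) brute <- brute + counts[i, j] * log(probs[i, j])
  expect_equal(composite_loglik(obs, probs), brute, tolerance = 1e-12)
  # uniform probabilities give total * log(1/E) exactly
  E <- 7
  pu <- matrix(1 / E, 3, 3); pu[c(1, 9)] <- 0
  expect_equal(composite_loglik(obs, pu), obs$total * log(1 / E),
               tolerance = 1e-12)
  expect_lte(composite_loglik(obs, pu), 0)
  expect_error(composite_loglik(obs, matrix(1, 2, 2)), "shapes differ")
})

test_that("fit with everything fixed returns the direct evaluation", {
  m <- scenario_preset("pair_IM_constant", ne1 = 3000, ne2 = 3000,
                       ne_anc = 3000, t_split = 2000, m = 5e-5)
  sim <- simulate_dataset(m, c(P1 = 4, P2 = 4), n_loci = 300,
                          locus_length = 1000, seed = 41)
  obs <- joint_sfs(as_genotype_matrix(sim), c("P1", "P2"),
                   seq_length = 300 * 1000)
  truthpt <- list(ne1 = 3000, ne2 = 3000, ne_anc = 3000, t_split = 2000,
                  m = 5e-5)
  fit <- fit_model(obs, "pair_IM_constant", c(P1 = 4, P2 = 4),
                   sims_per_eval = 500, seed = 42, fixed = truthpt)
  expect_equal(unname(fit$par[names(truthpt)]), unname(unlist(truthpt)))
  direct <- composite_loglik(
    obs, expected_sfs(m, c(P1 = 4, P2 = 4), n_sims = 500, seed = 42))
  expect_equal(fit$loglik, direct, tolerance = 1e-9)
  # seeded fits are reproducible
  f1 <- fit_model(obs, "pair_IM_constant", c(P1 = 4, P2 = 4),
                  n_starts = 1, max_iters = 5, sims_per_eval = 300,
                  seed = 77)
  f2 <- fit_model(obs, "pair_IM_constant", c(P1 = 4, P2 = 4),
                  n_starts = 1, max_iters = 5, sims_per_eval = 300,
                  seed = 77)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("model ranking and AIC follow their definitions", {
  f1 <- structure(list(label = "pair_IM_constant", loglik = -100,
                       obs_total = 50), class = "fit_result")
  f2 <- structure(list(label = "pair_IM_recent", loglik = -98,
                       obs_total = 50), class = "fit_result")
  r <- model_select(list(f1, f2), "maxCL")
  expect_equal(r$label[1], "pair_IM_recent")
  expect_equal(r$delta, c(0, 2))
  rA <- model_select(list(f1, f2), "AIC")
  expect_equal(rA$aic,
               -2 * rA$loglik + 2 * rA$k)
  # duplicate fits tie with stable order
  rT <- model_select(list(f1, f1), "maxCL")
  expect_equal(rT$delta, c(0, 0))
  f3 <- structure(list(label = "pair_IM_recent", loglik = -98,
                       obs_total = 51), class = "fit_result")
  expect_error(model_select(list(f1, f3)), "different observed")
})

test_that("parameter scaling converts and calibrates linearly", {
  fit <- structure(list(label = "pair_IM_constant",
                        par = c(ne1 = 5000, ne2 = 4000, ne_anc = 6000,
                                t_split = 356, m = 1e-4)),
                   class = "fit_result")
  sc <- scale_params(fit, generation_time = 10)
  expect_equal(sc$value[sc$param == "t_split"], 3560)
  sc1 <- scale_params(fit, generation_time = 1)
  expect_equal(sc1$value[sc1$param == "t_split"], 356)
  # calibration multiplies every time linearly
  fit2 <- fit
  fit2$par <- c(fit$par, t_mig = 100)
  names(fit2$par)[6] <- "t_mig"
  cal <- scale_params(fit2, generation_time = 10,
                      calibrate = list(param = "t_split", age_years = 7120))
  expect_equal(cal$value[cal$param == "t_split"], 7120)
  expect_equal(cal$value[cal$param == "t_mig"], 2000)
  expect_error(scale_params(fit, calibrate = list(param = "nope",
                                                  age_years = 1)),
               "calibration node")
})

test_that("direction test recovers pulses and stays quiet on null data", {
  base <- demographic_model(
    data.frame(name = c("P1", "P2", "ANC"), ne = c(10000, 5000, 15000)),
    list(ev_split(640000, "P1", "ANC"), ev_split(640000, "P2", "ANC")))
  samp <- c(P1 = 8, P2 = 8)
  # pulsed data: the true donor attains a far higher composite likelihood
  # and the pulse proportion is recovered near its simulated value
  truth <- introflow:::add_pulse(base, 180, "P1", "P2", 0.1)
  simp <- simulate_dataset(truth, samp, n_loci = 1200, locus_length = 300,
                           seed = 7001)
  obsp <- joint_sfs(as_genotype_matrix(simp), c("P1", "P2"),
                    seq_length = 1200 * 300)
  dtp <- direction_test(obsp, base, samp, pulse_time_bounds = c(10, 3000),
                        sims_per_eval = 1500, max_iters = 40, n_starts = 2,
                        seed = 7101)
  expect_equal(dtp$direction, "P1->P2")
  expect_lt(abs(dtp$fit_12$par[["phi"]] - 0.1), 0.05)
  # null data: the likelihood difference collapses and both directions fit
  # a vanishing pulse proportion
  sim0 <- simulate_dataset(base, samp, n_loci = 1200, locus_length = 300,
                           seed = 8001)
  obs0 <- joint_sfs(as_genotype_matrix(sim0), c("P1", "P2"),
                    seq_length = 1200 * 300)
  dt0 <- direction_test(obs0, base, samp, pulse_time_bounds = c(10, 3000),
                        sims_per_eval = 1500, max_iters = 40, n_starts = 2,
                        seed = 8101)
  expect_lt(abs(dt0$delta_cl), abs(dtp$delta_cl) / 100)
  expect_lt(dt0$fit_12$par[["phi"]], 0.01)
  expect_lt(dt0$fit_21$par[["phi"]], 0.01)
})

test_that("the composite likelihood prefers the simulating parameters", {
  truth <- scenario_preset("pair_IM_constant")
  doubled <- scenario_preset("pair_IM_constant", ne1 = 10000, ne2 = 10000,
                             ne_anc = 15000, t_split = 8000, m = 1e-4)
  samp <- c(P1 = 4, P2 = 4)
  diffs <- sapply(1:10, function(rep) {
    sim <- simulate_dataset(truth, samp, n_loci = 800, locus_length = 300,
                            seed = 900 + rep)
    obs <- joint_sfs(as_genotype_matrix(sim), c("P1", "P2"),
                     seq_length = 800 * 300)
    s <- 950 + rep
    composite_loglik(obs, expected_sfs(truth, samp, n_sims = 2000,
                                       seed = s)) -
      composite_loglik(obs, expected_sfs(doubled, samp, n_sims = 2000,
                                         seed = s))
  })
  expect_gt(mean(diffs), 0)
})
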