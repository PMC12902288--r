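# Structured-coalescent engine: neutral expectations, determinism, event
# semantics, presets, degradation and VCF round trips.

single_deme <- function(ne = 10000, mu = 6.675e-8)
  demographic_model(data.frame(name = "A", ne = ne), list(),
                    mutation_rate = mu)

test_that("model validation rejects malformed demographies", {
  expect_error(demographic_model(data.frame(name = "A", ne = -1), list()),
               "Ne")
  expect_error(demographic_model(data.frame(name = c("A", "B"),
                                            ne = c(100, 100)), list()),
               "root")
  expect_error(
    demographic_model(data.frame(name = c("A", "B"), ne = c(100, 100)),
                      list(ev_pulse(10, "A", "B", 1.5),
                           ev_split(20, "A", "B"))),
    "phi")
  expect_error(
    demographic_model(data.frame(name = c("A", "B"), ne = c(100, 100)),
                      list(ev_split(20, "A", "C"))),
    "unknown deme")
  expect_error(
    demographic_model(data.frame(name = c("A", "B"), ne = c(100, 100)),
                      list(ev_split(20, "A", "B"), ev_split(10, "B", "A"))),
    "non-decreasing")
})

test_that("isolated demes with no root path raise a structural error", {
  demes <- data.frame(name = c("A", "B"), ne = c(1000, 1000))
  m <- structure(list(demes = demes, events = list(),
                      mutation_rate = 1e-8, generation_time = 10,
                      root = "A"), class = "demographic_model")
  expect_error(simulate_dataset(m, c(A = 2, B = 2), n_loci = 1, seed = 1),
               "unreachable")
})

test_that("pairwise coalescence time and diversity match neutral theory", {
  ne <- 10000; mu <- 1e-8; L <- 1000; n_loci <- 2000
  sim <- simulate_dataset(single_deme(ne, mu), c(A = 1), n_loci = n_loci,
                          locus_length = L, seed = 42)
  t2 <- sim$truth$tmrca
  se_t2 <- sd(t2) / sqrt(n_loci)
  expect_lt(abs(mean(t2) - 2 * ne), 3 * se_t2)
  # E[pi] = 4 Ne mu per site; per-locus pairwise differences / L
  pi_hat <- sum(sim$hap_geno[1, ] != sim$hap_geno[2, ]) / (n_loci * L)
  # MC SE from per-locus difference counts (single contig, loci laid
  # end to end)
  per_locus <- tabulate((sim$sites$pos - 1) %/% L + 1, nbins = n_loci)
  se_pi <- sd(per_locus / L) / sqrt(n_loci)
  expect_lt(abs(pi_hat - 4 * ne * mu), 3 * se_pi)
})

test_that("segregating sites match Watterson's expectation for n = 6", {
  ne <- 5000; mu <- 1e-7; L <- 500; n_loci <- 2000
  sim <- simulate_dataset(single_deme(ne, mu), c(A = 3), n_loci = n_loci,
                          locus_length = L, seed = 7)
  a1 <- sum(1 / (1:5))
  per_locus <- tabulate((sim$sites$pos - 1) %/% L + 1, nbins = n_loci)
  expect_equal(sum(per_locus), nrow(sim$sites))
  se <- sd(per_locus) / sqrt(n_loci)
  expect_lt(abs(mean(per_locus) - 4 * ne * mu * a1 * L), 3 * se)
})

test_that("two isolated demes give Dxy about 2 mu (t + 2 Ne_anc)", {
  ne <- 5000; mu <- 1e-7; t_split <- 20000; L <- 500; n_loci <- 1500
  m <- demographic_model(
    data.frame(name = c("A", "B", "ANC"), ne = c(ne, ne, ne)),
    list(ev_split(t_split, "A", "ANC"), ev_split(t_split, "B", "ANC")),
    mutation_rate = mu)
  sim <- simulate_dataset(m, c(A = 1, B = 1), n_loci = n_loci,
                          locus_length = L, seed = 12)
  # haplotypes 1:2 are deme A, 3:4 deme B
  d <- colMeans(rbind(sim$hap_geno[1, ] != sim$hap_geno[3, ],
                      sim$hap_geno[1, ] != sim$hap_geno[4, ],
                      sim$hap_geno[2, ] != sim$hap_geno[3, ],
                      sim$hap_geno[2, ] != sim$hap_geno[4, ]))
  locus_of <- (sim$sites$pos - 1) %/% L + 1
  per_locus <- vapply(seq_len(n_loci), function(i)
    sum(d[locus_of == i]), numeric(1)) / L
  dxy <- mean(per_locus)
  se <- sd(per_locus) / sqrt(n_loci)
  expect_lt(abs(dxy - 2 * mu * (t_split + 2 * ne)), 3 * se)
})

test_that("identical model, sampling and seed reproduce byte-identical data", {
  m <- scenario_preset("study_pulse")
  s1 <- simulate_dataset(m, c(HS = 2, TP_E = 2, J = 1), n_loci = 50,
                         locus_length = 300, seed = 99, n_contigs = 5)
  s2 <- simulate_dataset(m, c(HS = 2, TP_E = 2, J = 1), n_loci = 50,
                         locus_length = 300, seed = 99, n_contigs = 5)
  expect_identical(s1$hap_geno, s2$hap_geno)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$truth$tmrca, s2$truth$tmrca)
})

test_that("a phi = 0 pulse event reproduces the no-event random stream", {
  base <- demographic_model(
    data.frame(name = c("A", "B", "ANC"), ne = c(2000, 2000, 2000)),
    list(ev_split(5000, "A", "ANC"), ev_split(5000, "B", "ANC")),
    mutation_rate = 1e-7)
  with_null <- demographic_model(
    base$demes,
    c(list(ev_pulse(100, "A", "B", 0)), base$events),
    mutation_rate = 1e-7)
  s1 <- simulate_dataset(base, c(A = 2, B = 2), n_loci = 40,
                         locus_length = 500, seed = 5)
  s2 <- simulate_dataset(with_null, c(A = 2, B = 2), n_loci = 40,
                         locus_length = 500, seed = 5)
  expect_identical(s1$hap_geno, s2$hap_geno)
  expect_identical(s1$sites$pos, s2$sites$pos)
})

test_that("a phi = 1 pulse relocates every lineage of the destination", {
  m <- demographic_model(
    data.frame(name = c("A", "B", "ANC"), ne = c(2000, 2000, 2000)),
    list(ev_pulse(100, "A", "B", 1),
         ev_split(5000, "A", "ANC"), ev_split(5000, "B", "ANC")),
    mutation_rate = 1e-7)
  sim <- simulate_dataset(m, c(A = 2, B = 3), n_loci = 30,
                          locus_length = 500, seed = 3)
  expect_true(all(sim$truth$pulse_moved == sim$truth$pulse_present))
  # B samples 3 diploids = 6 lineages; none can have coalesced by t = 100
  # with Ne = 2000 in every locus, but at least they are all accounted for
  expect_true(all(sim$truth$pulse_present <= 6))
})

test_that("presets are structurally correct", {
  expect_error(scenario_preset("nope"), "valid presets")
  null <- scenario_preset("study_null")
  pulses <- Filter(function(e) e$type == "pulse", null$events)
  expect_equal(vapply(pulses, `[[`, numeric(1), "prop"), 0)
  # ingroup demes all merge before the outgroup join
  splits <- Filter(function(e) e$type == "split", null$events)
  t_join_j <- max(vapply(splits, `[[`, numeric(1), "time"))
  ingroup <- c("TP_E", "TP_M", "TP_W", "HS")
  t_ingroup <- vapply(ingroup, function(d)
    min(vapply(Filter(function(e) e$child == d, splits), `[[`,
               numeric(1), "time")), numeric(1))
  expect_true(all(t_ingroup < t_join_j))

  # constant: one un-interrupted migration epoch over [0, t_split)
  cons <- scenario_preset("pair_IM_constant")
  tt <- c(1, 1000, 2500, 3999)
  expect_true(all(oracle_pair_mig_rate(cons, tt) > 0))
  expect_equal(length(unique(oracle_pair_mig_rate(cons, tt))), 1L)
  # early and recent partition [0, t_split) complementarily
  early <- scenario_preset("pair_IM_early")
  recent <- scenario_preset("pair_IM_recent")
  re <- oracle_pair_mig_rate(early, tt)
  rr <- oracle_pair_mig_rate(recent, tt)
  expect_true(all((re > 0) == !(rr > 0)))
  expect_true(any(re > 0) && any(rr > 0))
})

test_that("derived-allele counts stay within (0, 2n) and positions increase", {
  sim <- simulate_dataset(scenario_preset("study_null"),
                          c(HS = 3, TP_E = 3, TP_M = 2, TP_W = 2, J = 2),
                          n_loci = 60, locus_length = 300, seed = 21,
                          n_contigs = 4)
  dc <- colSums(sim$hap_geno)
  expect_true(all(dc >= 1 & dc <= nrow(sim$hap_geno) - 1))
  for (ct in unique(sim$sites$contig)) {
    p <- sim$sites$pos[sim$sites$contig == ct]
    expect_true(all(diff(p) > 0))
  }
})

test_that("degradation masks at the requested rate and sets QUAL", {
  sim <- simulate_dataset(single_deme(5000, 1e-7), c(A = 10), n_loci = 100,
                          locus_length = 1000, seed = 8)
  # identity at rate 0
  d0 <- degrade_dataset(sim, missing_rate = 0, qual_dist = 60, seed = 1)
  expect_null(d0$miss_mask)
  expect_true(all(d0$sites$qual == 60))
  expect_identical(as_genotype_matrix(d0)$geno[, 1],
                   as_genotype_matrix(sim)$geno[, 1])
  # binomial bound at rate 0.5
  d5 <- degrade_dataset(sim, missing_rate = 0.5, seed = 2)
  ncalls <- length(d5$miss_mask)
  frac <- mean(d5$miss_mask)
  ci <- qnorm(0.995) * sqrt(0.25 / ncalls)
  expect_gt(ncalls, 5000)
  expect_lt(abs(frac - 0.5), ci)
  expect_error(degrade_dataset(sim, missing_rate = 1, seed = 1), "missing_rate")
})

test_that("VCF round trip is lossless and honors format details", {
  sim <- simulate_dataset(scenario_preset("study_null"),
                          c(HS = 2, TP_E = 2, TP_M = 2, TP_W = 2, J = 2),
                          n_loci = 95, locus_length = 300, seed = 31,
                          n_contigs = 19)
  sim <- degrade_dataset(sim, missing_rate = 0.1, qual_dist = 60, seed = 32)
  vcf <- tempfile(fileext = ".vcf"); pm <- tempfile(fileext = ".tsv")
  write_vcf(sim, vcf, pm)
  lines <- readLines(vcf)
  expect_length(grep("^##contig", lines), 19)
  expect_true(any(grepl("./.", lines, fixed = TRUE)))
  expect_true(file.exists(paste0(vcf, ".truth.json")))

  gm <- read_vcf(vcf, pm)
  ref <- as_genotype_matrix(sim)
  expect_equal(unname(gm$geno), unname(ref$geno))
  expect_equal(gm$sites$pos, ref$sites$pos)
  expect_equal(gm$sites$contig, ref$sites$contig)
  expect_equal(gm$samples$pop, ref$samples$pop)
  expect_equal(gm$contigs$length, ref$contigs$length)
})
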