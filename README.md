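# introflow

Detection and characterization of interspecific introgression from
multi-sample SNP data, built around a two-species orchid system: a local
lithophytic species (HS), an invasive congener with three ecotypes (TP_E,
TP_M, TP_W) and an outgroup (J). The package answers three questions: is
there an excess of shared derived alleles between HS and one ecotype
(introgression rather than lineage sorting), in which direction did the
gene flow run, and what do the affected genomic regions look like.

For whom: population geneticists analyzing VCFs of biallelic SNPs with a
sample-to-population map, and methodologists who want a self-contained,
seeded test-bed — the package ships its own structured-coalescent
simulator, so every statistic can be exercised against data with known
truth.

## What is implemented

* **Simulator** — structured coalescent with population splits, epoch
  migration, instantaneous admixture pulses (proportion φ), infinite-sites
  mutation, RAD-seq-like missingness/QUAL degradation, VCFv4.2 output;
  presets for the study system and four two-population
  isolation-with-migration templates.
* **Genotypes** — VCF + popmap ingestion, the study's variant filters
  (missingness < 20%, QUAL > 30, MAF > 0.05, strict inequalities),
  outgroup polarization, window tiling.
* **Introgression** — Patterson's D,
  `D = (ΣABBA − ΣBABA)/(ΣABBA + ΣBABA)` with
  `abba = (1−p1)p2p3(1−p4)`, `baba = p1(1−p2)p3(1−p4)`, weighted
  delete-one block-jackknife Z; windowed f_dM (dynamic-donor denominator,
  bounded in [−1, 1]) with top-quantile outlier calling; f3(C; A, B) =
  mean (c−a)(c−b) with Z < −3 as the admixture call.
* **Popgen** — windowed π, Dxy, Hudson FST, Tajima's D, Fu & Li's
  D/F/D*/F*, Ho/He, SNP density; LD-decay curves (composite r²);
  Z(FST) × log10(θπ-ratio) selection scan.
* **Divergence** — NG86 Ka/Ks with pathway averaging, Jukes–Cantor
  correction and Fisher exact test; molecular clock `T = K_S/(2r)`.
* **Demography** — unfolded joint SFS (with hypergeometric projection),
  Monte-Carlo expected spectra by branch-length accumulation, composite
  likelihood with a SNP-count anchor, multi-start Nelder–Mead fitting of
  the four gene-flow models, model ranking, pulse-direction test,
  parameter scaling to absolute units.
* **Bayes** — power posteriors `prior × likelihood^β` at Gauss–Legendre
  nodes (K = 16 default), adaptive random-walk Metropolis,
  thermodynamic-integration log marginal likelihood `M = Σ w_k E_k / 2`,
  Bayes factors `B = exp(M1 − M0)` with the decisive `B > 100` call.
* **Pipeline** — YAML-configured end-to-end run
  (`validate_config()` / `run_pipeline()`) with per-stage TSV/JSON
  outputs and a reproducibility manifest.

## Worked example

Simulate the study design with a 10% HS → TP_E pulse, filter, and scan:

```r
library(introflow)

model <- scenario_preset("study_pulse", phi = 0.1)
sim <- simulate_dataset(model,
                        c(HS = 10, TP_E = 9, TP_M = 8, TP_W = 8, J = 5),
                        n_loci = 950, locus_length = 300, seed = 20,
                        n_contigs = 19)
sim <- degrade_dataset(sim, missing_rate = 0.05, seed = 21)
gm  <- filter_variants(as_genotype_matrix(sim))
nrow(gm$sites)
#> [1] 62349

fr <- allele_freqs(gm, c(P1 = "TP_W", P2 = "TP_E", P3 = "HS", O = "J"))
patterson_d(fr)
#> D = 0.3371  SE = 0.0353  Z = 9.54  (ABBA = 1684.6, BABA = 835.2, 63 blocks)

fdm <- fdm_windows(fr, make_windows(gm$contigs, 1000), min_sites = 5)
out <- fdm_outliers(fdm, 0.95)
c(windows = nrow(fdm), mean_fdm = round(mean(fdm$fdm), 3),
  threshold = round(out$threshold, 3), outliers = nrow(out$outliers))
#>   windows  mean_fdm threshold  outliers
#>   285.000     0.068     0.217    15.000

bayes_factor(-35226.45, -35236.07)
#> B = 1.51e+04 (M1 = -35226.45, M0 = -35236.07) -> model 1
```

Reading the output: D = 0.34 with Z = 9.5 (> 3) flags a significant
excess of TP_E–HS allele sharing in the quartet (TP_W, TP_E; HS, J); the
window-level f_dM mean is positive with 15 windows above the top-5%
threshold, localizing the signal; and the Bayes factor between the two
direction-of-flow models, computed from their log marginal likelihoods,
decisively supports the model with the local species as donor
(B ≈ 1.5 × 10⁴ > 100). Under `scenario_preset("study_null")` (φ = 0) the
same analysis returns |Z| < 3.

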