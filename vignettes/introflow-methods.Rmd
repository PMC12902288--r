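---
title: "Detecting and characterizing unidirectional introgression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing unidirectional introgression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introflow)
```

# The scientific problem

`introflow` implements the statistical machinery for asking whether a
species that recently colonized a new habitat carries genomic material
introgressed from a distantly related local congener, in which direction
the gene flow ran, and what the affected regions look like. The motivating
system is a pair of *Dendrobium* orchids: a lithophytic local species (here
called HS) and an invasive congener whose populations fall into three
ecotypes (TP_E, TP_M, TP_W), with a further outgroup (J) used to polarize
alleles. The two species diverged roughly 6.4 million years ago, so
incomplete lineage sorting between them is negligible and an excess of
shared derived alleles between HS and one ecotype is strong evidence of
secondary contact.

The package covers five layers of that analysis:

1. a structured-coalescent simulator that generates SNP data with the
   assumed statistical structure (splits, migration epochs, admixture
   pulses, RAD-seq-like degradation);
2. genotype handling: VCF ingestion, the study's variant filters,
   outgroup polarization, window tiling;
3. introgression statistics: Patterson's D with weighted block-jackknife
   significance, windowed f_dM, and the f3 admixture statistic;
4. windowed population-genetic descriptors (pi, Dxy, Hudson's FST,
   Tajima's D, Fu & Li's tests, LD decay, Z(FST)/log10 pi-ratio selection
   scans) and NG86 Ka/Ks with the molecular-clock identity T = K_S/(2r);
5. demographic inference: joint-SFS composite likelihood over four
   two-population gene-flow models, a pulse-direction test, and
   thermodynamic-integration Bayes factors.

# The coalescent engine

## Model

A `demographic_model` is a set of demes with constant diploid effective
sizes and a backwards-time event schedule. Three event types exist: a
*split* merges a child deme into its parent; a *pulse* moves each lineage
of the forward-time recipient into the donor independently with
probability phi; a *migration change* installs a new backwards migration
matrix from that time onward. Between events the engine runs a standard
exponential-waiting-time structured coalescent: within deme i with k
lineages, pairs coalesce at rate k(k-1)/(4 Ne_i) per generation, and each
lineage in i migrates to j at rate m_ij.

Waiting times are generated by the accumulated-hazard construction: a
single unit-rate exponential hazard is spent across schedule boundaries.
Because the exponential is memoryless this is exact, and it has a useful
engineering consequence: a schedule event consumes no randomness, so a
model containing a `phi = 0` pulse reproduces the random stream of the
model without the event, byte for byte. Each locus is seeded from the root
seed by a fixed counter scheme, making loci exchangeable replicates and
entire datasets reproducible from `(model, sampling, seed)`.

Loci are non-recombining and independent — the regime in which both the
D/f_dM statistics and the SFS composite likelihood are derived. Mutations
follow the infinite-sites model: Poisson with mean mu x locus length x
total branch length, placed on branches proportionally to length, at
unique integer positions (uniform within the locus). The ancestral allele
is written "A" and the derived allele "T"; the labels are arbitrary.

Event times must be non-decreasing rather than strictly increasing: a
clean merge of two sister demes into a named ancestor is expressed as two
splits at the same instant, applied in listed order.

## The study presets

`scenario_preset("study_pulse")` encodes the five-deme system. Published
anchors: species split 6.4 Mya, TP_W separation 36.93 kya, TP_E/TP_M
separation 3.56 kya, mutation rate 6.675e-8 per site per generation,
10-year generations, effective sizes within the 1 000–60 000 haploid
sampling range. Quantities the source data do not pin down were fixed once
at values a population geneticist would call realistic, and are not tuned:

* per-deme diploid sizes 5 000 (TP ecotypes), 10 000 (HS, J, TP ancestor),
  15 000 (deeper ancestors);
* the outgroup joins at twice the species-split age (12.8 Mya);
* a window of weak symmetric migration (1e-5 per lineage per generation)
  between HS and the common ancestor of the TP ecotypes spans
  36.93–140 kya, the inferred Last-Interglacial contact. This matters for
  testing: with strictly zero historical contact and a 6.4-My split,
  essentially no site is simultaneously polymorphic in both species, the
  ABBA/BABA denominators collapse, and D is undefined. The ancestral
  contact creates shared variation that is symmetric with respect to the
  TP ecotypes, so the null expectation of D for any quartet of them
  remains zero;
* the introgression pulse HS -> TP_E sits at 180 generations (~1.8 kya,
  inside the TP_E epoch) with default `phi = 0.1`.

`"study_null"` is the same model with `phi = 0`. The four `pair_IM_*`
presets are two-deme isolation-with-migration templates that differ only
in where migration sits on `[0, t_split)`: everywhere (`constant`), the
older half (`early`), the recent half (`recent`), or both halves at
different rates (`different`). Defaults: Ne 5 000/5 000, ancestor 7 500,
split 4 000 generations, rate 5e-5, epoch boundary at half the split time.

## RAD-seq-like degradation

`degrade_dataset` masks diploid calls independently at a fixed rate and
draws per-site QUAL scores (default gamma, mean ~63). This mimics the
sparse, quality-heterogeneous genotype matrices of reduced-representation
sequencing; it does not attempt allele dropout correlated with restriction
sites, sequencing error in called genotypes, or depth-dependent bias, so
passing tests say nothing about those failure modes on real data.

# Genotypes, filters, windows

Coordinates are BED-like internally (0-based half-open) and converted at
the VCF boundary. The variant filters follow the study's thresholds with
deliberately strict inequalities — retained sites have missingness
strictly below 20%, QUAL strictly above 30, and minor-allele frequency
strictly above 0.05 computed jointly over all samples. The boundary
semantics are worth stating because an off-by-one here changes retained
site counts: a site at MAF exactly 0.05 is excluded. Filtering is
idempotent, and a site failing several rules increments each rule's
exclusion counter.

Polarization declares the outgroup's major allele ancestral. Sites where
the outgroup is exactly 50/50 are dropped rather than randomly resolved —
determinism is worth more than the handful of sites. Window tiling is
half-open, non-overlapping by default, and discards the trailing partial
window, so a 25-kb contig yields exactly two 10-kb windows.

# Introgression statistics

Site patterns use outgroup-polarized population frequencies:
`abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`. Patterson's
D is the genome-wide ratio `(sum ABBA - sum BABA)/(sum ABBA + sum BABA)`.
One sign table is used everywhere: positive `D(P1, P2; P3, O)` means
excess P2–P3 sharing; for the scan arrangement `(TP_W, TP_E; HS, J)` a
recent HS -> TP_E pulse therefore drives D and f_dM positive.

Significance comes from a weighted delete-one block jackknife over
consecutive SNP blocks (default 1 000 sites; 500 for f3), with block
weights equal to informative content (ABBA+BABA). Writing the genome-wide
ratio as a weighted mean of block ratios makes the delete-one algebra
exact, and with equal weights the standard error reduces to the classical
`s/sqrt(n)` of the mean — the identity the tests pin down. `Z > 3` is the
conventional significance call.

The windowed f_dM uses the dynamic-donor denominator: per site the
numerator is ABBA−BABA, and the denominator substitutes the donor
frequency `max(p2, p3)` into both the P2 and P3 slots when `p2 >= p1`
(mirrored and negated otherwise), which bounds the window statistic in
[-1, 1] and makes it symmetric for donor sharing with P1 versus P2.
Windows with fewer than five usable sites are dropped, as are
zero-denominator windows (both counted). Outlier calling takes the
empirical type-7 quantile and keeps windows strictly above it, so an
all-ties input yields no outliers.

f3(C; A, B) is the plain mean of `(c-a)(c-b)` with block-jackknife
standard errors; a significantly negative value (Z < -3) labels C
admixed. No finite-sample heterozygosity correction is applied — the
worked arithmetic of the statistic is the definition here — which biases
f3 upward slightly at small sample sizes and is therefore conservative
for admixture detection.

# Windowed descriptors

Per-window nucleotide diversity is the mean over genotyped SNP sites of
`2p(1-p) n/(n-1)`. The denominators are *accessible sites* (the genotyped
SNPs in the window), not physical window length: RAD data are sparse, and
physical denominators would deflate pi by the (unknown) fraction of
unsequenced sites. SNP density carries the physical-window information
instead. Dxy is the mean of `px(1-py) + py(1-px)`.

FST is Hudson's ratio of averages, `1 - mean(Hw)/mean(Hb)`, with the
within-population term taken as uncorrected expected heterozygosity
`2p(1-p)`. The uncorrected form is chosen deliberately so that two
populations with identical frequency vectors give exactly FST = 0; with
the n/(n-1) correction the same configuration returns a small negative
value, which is statistically defensible but confusing in a scan report.
The corrected quantity is still available — it is exactly the pi column.
Weir–Cockerham is not implemented; Hudson's estimator is symmetric in the
populations, which the tests assert.

Tajima's D uses the 1989 constants; Fu & Li's D and F contrast total
mutations with derived singletons (requiring polarization), and the
starred variants use singletons of either allele. All four use the
published normalizing constants, checked against independently coded
oracles and sign logic (all-external mutations drive D negative; absence
of singletons drives it positive). Under the infinite-sites simulator
eta = S.

LD decay uses composite (genotype-dosage correlation) r², as appropriate
for unphased VCFs, over intra-contig pairs within a maximum distance,
binned by distance; the half-decay distance is the smallest bin midpoint
whose mean r² is at most half the maximum bin mean. For unlinked loci
E[r²] is approximately 1/n, which the simulator-based test checks.

The selection scan Z-transforms window FST and takes log10 of the pi
ratio; candidates are windows in the top 5% of *both* scores. The
conjunction is the default because it is the stricter reading; the union
is available via `mode = "either"`. Windows with zero denominator pi are
excluded from the ratio ranking and counted.

# Ka/Ks and the molecular clock

`kaks_ng86` implements Nei–Gojobori (1986) counting: per-codon synonymous
site fractions from the universal code (changes creating stop codons count
as nonsynonymous, so N + S equals the alignment length), differences
averaged over equally weighted minimal mutational pathways with
stop-containing pathways discarded, Jukes–Cantor correction
`-(3/4) log(1 - 4p/3)` (undefined at p >= 3/4, returned as missing), and a
two-sided Fisher exact test on the rounded 2x2 count table. A
pathway-enumeration oracle in the test suite verifies the averaging. The
codon-model machinery of likelihood methods (YN00-style) is out of scope:
the downstream use is the classification omega < 1 with a Fisher p-value,
for which NG86 is sufficient and transparent.

`clock_convert` solves `T = K_S/(2r)` for whichever of the three
quantities is missing and reports the per-generation rate. The package
treats the per-generation mutation rate used elsewhere (6.675e-8) as a
configurable constant, not something derived: with K_S = 1 and T = 74 My
the identity gives 6.757e-9 per year, i.e. 6.757e-8 per 10-year
generation, which is close to but not exactly the constant — the inputs
behind the final rounding are not recoverable, so no derivation is
pretended.

# Demographic inference

## Composite likelihood on the joint SFS

The unfolded joint SFS of a population pair counts SNPs by derived-allele
counts; fixed-fixed corners are masked. Hypergeometric projection to
smaller sample sizes accumulates each site's expectation over
down-sampled configurations, allowing sites with missing calls to
contribute. The composite log-likelihood is the multinomial
`sum(obs log p)` over unmasked entries, plus — when the observation knows
how many sites were surveyed — a Poisson term on the total SNP count.
That term matters: normalized spectrum shape alone leaves the overall
time/size scale of a model nearly unidentified (rescaling all sizes and
times leaves entry probabilities almost unchanged), and anchoring on the
observed SNP density restores it. For empirical data whose accessible
length is unknown the term is simply absent, and one parameter should be
fixed by external calibration instead.

## Expected spectra by branch accumulation

The expected SFS under candidate parameters is Monte Carlo over simulated
genealogies, but not by counting simulated mutations: for each genealogy
every branch contributes its length to the entry indexed by the derived
leaf counts of the two demes. This is the exact conditional expectation of
the infinite-sites spectrum given the genealogy (Rao–Blackwellization over
mutation placement), removes all mutation-sampling noise, and makes the
desk-scale likelihood surfaces usable: at 5 000 genealogies the
log-likelihood noise drops by roughly an order of magnitude compared with
mutation counting at equal cost. The mutation-dropping estimator is
retained as `method = "mutation"` and the test suite checks the two agree.
A pseudocount floor of `0.5/total` on unobserved entries prevents log(0);
its effect vanishes as the simulation batch grows.

## Optimization

`fit_model` maximizes the composite likelihood over log-transformed
parameters (logit for the epoch-boundary fraction) with Nelder–Mead under
common random numbers, in three stages:

1. a random log-uniform screen of candidate points;
2. Nelder–Mead from the best screened candidates, with starts
   *stratified over split time*: the surface has a known ridge (an older
   split with more migration mimics a recent split with less), and
   unstratified random starts can all fall into one basin;
3. basin comparison and polish: all stage-2 endpoints are re-evaluated on
   a single larger-batch stream (`refine_factor` x `sims_per_eval`) and
   the two best are polished there. Per-start optima overfit their own
   random stream by roughly the evaluation noise, so this final
   common-stream comparison is what makes split-time estimates reliable.

Bounds default to the published sampling ranges (sizes 1 000–60 000
haploid, migration 1e-5–1e-2 per generation); the divergence-time bounds
are declared here (100–100 000 generations) since the source range is
stated in units that do not survive scrutiny. Model choice is by maximum
composite likelihood or AIC = -2 CL + 2k; because the four gene-flow
models are migration-epoch variants of one template, the comparison is
between nested-like structures. These settings are scaled down by roughly
an order of magnitude from the cluster-scale budgets typical for this kind
of inference (hundreds of independent runs with 2e5 simulations per
likelihood); the recovery experiments in the test suite define what the
desk-scale settings can resolve: with ~20 000 SNPs from short independent
loci, split time and sizes are recovered within ±25% in most replicates,
while migration rate remains the softest parameter.

`direction_test` adds a pulse in each direction to a fixed base demography
and fits only the pulse parameters (proportion and time). Holding the base
fixed is a deliberate desk-scale choice: it isolates the directional
signal, which lives in the asymmetric corners of the joint SFS (sites
segregating in the recipient where the donor is fixed), and in the
experiments here the correct direction wins by thousands of log-units
while truly pulse-free data give near-zero differences and vanishing
fitted proportions. An optional thermodynamic-integration Bayes factor
between the two directions uses the beta(6, 200) prior on the proportion.
Treating a composite likelihood as a true likelihood inside that Bayes
factor overstates evidence under linkage; the number should be read as a
ranking device, not a calibrated posterior odds.

`scale_params` converts generations to years (default 10-year generations)
and can recalibrate linearly so a named node matches an absolute age
(6.4 My for the species split is the system's convention).

# Marginal likelihoods and Bayes factors

`power_schedule(K)` places K Gauss–Legendre nodes on (-1, 1) and maps them
to inverse temperatures `beta = (x+1)/2`, keeping the original weights
(sum 2); the estimator `M = sum w_k E_k / 2` performs the interval change,
so a constant log-likelihood integrates exactly. K = 16 is the
conventional default. `mh_sample` is a componentwise Gaussian random-walk
Metropolis sampler targeting prior x likelihood^beta; proposal scales
adapt toward ~30% acceptance during burn-in only and are frozen afterward,
preserving detailed balance for the recorded samples. Monte-Carlo standard
errors use autocorrelation-adjusted effective sample sizes, and the
per-beta errors are propagated as independent (chains at different beta
are independent by construction; within-chain dependence is already in the
ESS). The expected log-likelihood should be non-decreasing in beta; a
violation beyond 3 SE is flagged, not failed, since short chains can
produce one legitimately.

The validation target is the conjugate normal model, whose evidence is
known in closed form; the test suite requires the TI estimate to sit
within three propagated standard errors of it across seeds. Bayes factors
are `B = exp(M1 - M0)` with the decisive-support convention `B > 100`. The
two printed worked examples of the motivating analysis reproduce by direct
computation: log marginals (-35226.45, -35236.07) give B = 1.51e4 and
(-31329.31, -31359.54) give B = 1.34e13, both supporting the model in
which the local species is the donor.

# Numerical choices and degenerate inputs

* Undefined D (no informative sites) is an error; a zero jackknife SE
  with non-zero D yields an infinite Z with a warning.
* Monomorphic windows keep `n_sites = 0` with missing statistics rather
  than disappearing.
* Tajima's D with S = 0 and Fu & Li with eta = 0 are missing, not errors;
  n < 4 haplotypes is an error.
* The Jukes–Cantor correction is missing at p >= 3/4; omega is missing at
  Ks = 0.
* Ties: outgroup 50/50 sites are dropped; outlier thresholds are strict.
* All stochastic entry points require an explicit seed; nothing falls
  back to the global RNG state silently (and the ambient RNG state is
  saved and restored around internal seeding).

# Problem sizes

The shipped experiments are sized for a single desktop core: simulator
calibration at 2 000 loci; D calibration at 20 + 20 replicates of a
950-locus, 35-sample RAD-like design; direction tests at 10 replicates of
1 200 loci; parameter recovery at 10 replicates of 7 000 loci with 4 000
(stage) / 24 000 (polish) genealogies per likelihood evaluation; TI
validation at 16 temperatures with short adaptive chains. Each scales up
by changing the corresponding argument; nothing in the implementation is
specific to these sizes.

# Known limitations

* No intra-locus recombination: loci are exchangeable replicates. Long
  phased haplotype statistics (iHS, XP-EHH) and recombination-rate
  inference are out of scope.
* The composite likelihood ignores linkage within loci; standard errors
  from it would be anticonservative, which is why the package reports
  likelihood differences and recovery rates rather than parametric CIs.
* Two-population demographic fits only; the five-deme study scenario is a
  simulation preset, not a fit target.
* Frequency-based D/f_dM assumes genotypes, not genotype likelihoods;
  low-coverage sampling variants are not implemented.
* The NG86/YN00 difference is immaterial for omega < 1 classification but
  NG86 underestimates Ks at high transition/transversion bias.
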