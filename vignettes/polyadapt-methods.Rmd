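---
title: "Models and methods behind polyadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind polyadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyadapt)
```

polyadapt implements the computational core of a climate-adaptation
population-genomics workflow for polyploid plant panels: subgenome-aware
k-mer curation of an allopolyploid assembly, allele-balance ploidy calling,
population-structure statistics, a cross-coalescence divergence rule, a
pulse-model local-ancestry HMM, regional-heritability variance partitioning,
and adaptation scans over GWAS regions. Every stage is exercised on
synthetic data whose generators are first-class, tested package code. This
vignette explains the models, the defaults, the numerical choices, and what
passing the simulation-based tests does and does not demonstrate.

## The synthetic panel

`gen_structured_genotypes()` draws a diverged multi-subpopulation panel from
the Balding–Nichols model: per site an ancestral frequency
$p \sim U(0.05, 0.95)$, per subpopulation a frequency
$p_k \sim \mathrm{Beta}\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$,
and per sample a diploidized dosage $\mathrm{Bin}(2, p_k)$. We chose
Balding–Nichols over a coalescent simulator deliberately: it parameterizes
$F_{ST}$ directly, which is the only differentiation statistic the
downstream stages consume, and it keeps the generator free of linkage
assumptions the estimators do not rely on. The default `fst_target = 0.27`
matches the differentiation scale of a strongly subdivided three-gene-pool
panel; sites default to evenly spaced positions on one chromosome (or on
`n_chroms` named `Chr01K`, `Chr01N`, ... for subgenome partitions).

What the generator does *not* emulate: linkage disequilibrium between sites
(sites are exchangeable given the frequencies), mutation-rate heterogeneity,
and selection. Tests that pass on these panels therefore validate estimator
algebra and calibration under drift-style differentiation, not robustness to
real LD structure.

`gen_admixed_cohort()` lays a two-state Markov chain along each haplotype:
switch probability $1 - e^{-g d}$ per interval of genetic length $d$, with
stationary donor probability $m$. Donor tract lengths are then approximately
exponential with mean $1/(g(1-m))$ Morgans, the classical single-pulse
approximation. Truth tracts are returned so the HMM can be scored against
the generator rather than against itself.

`gen_allele_balance()` draws per-site read pairs at Poisson total depth.
Tetraploid heterozygous sites read at variant-allele frequency 0.5;
octoploid libraries mix a 0.25-or-0.75 class with a 0.5 class. The mixture
weight is not a published quantity; we default to 0.9 on the 0.25/0.75
class. The arithmetic forces a weight in this region: at 60x depth a
VAF-0.5 site lands in the 0.48–0.52 band with probability ≈ 0.30, so any
weight much above ~0.1 on the 0.5 class would push an octoploid library's
band proportion far above the 0.035 decision threshold and the classifier
could never separate the two cytotypes it is known to separate. The weight
is exposed as `octo_weight` for sensitivity analysis.

`gen_rccr_series()` plants a sigmoidal collapse of the relative
cross-coalescence rate at a known generation. Noise is AR(1) across
segments (autocorrelation 0.85, marginal sd `noise_sd`): neighbouring time
segments of a cross-coalescence estimate are fitted from shared data and
their errors are strongly correlated, so independent per-segment noise
would be an unrealistically adversarial fixture for a rule that compares
adjacent segment differences.

`gen_phenotype()` simulates $y = u + v + e$ with $u$ drawn from the
genome-wide van Raden kinship and $v$ from the kinship of a designated
regional site set, each component rescaled so the realized variance
fractions equal the targets exactly (phenotypic variance 1). Exact scaling
removes one layer of Monte Carlo noise from parameter-recovery tests; it
means recovery tolerances measure estimator error, not generator jitter.

## K-mer curation of a duplicated assembly

`find_duplicate_kmers()` implements the duplicate-haplotype diagnostic:
canonical (strand-collapsed) 24-mers that occur *exactly twice* in the
whole contig set are evidence that two contigs are alternative haplotypes
of one locus. Contigs sharing at least `min_shared = 10` such k-mers are
linked; connected components form duplicate groups, and
`purge_haplotypes()` keeps the longest member of each group. The
exactly-twice rule makes repeats self-excluding: a k-mer seen three or more
times links nothing. The minimum-share threshold is our own guard (a single
shared k-mer is noise-prone); it is configurable. The accounting report
conserves base pairs exactly: total = retained + removed.

`diagnostic_kmers()` applies the asymmetric 15-mer rule (at most
`max_self = 1` hit in one homologue set, at least `min_other = 100` in the
other); `cluster_superfamilies()` takes connected components of the
share-a-15-mer graph; `assign_families()` clusters within superfamilies by
single linkage. For the pairwise similarity we use alignment-free k-mer
containment with the identity threshold mapped as $t^k$ — the probability
that a k-mer survives point divergence $1-t$ — rather than explicit
alignment: it is deterministic, dependency-free, and cleanly separates the
~1%-within-family from the ~15%-between-family divergence regimes the
pipeline needs to resolve. `jc_distance()` supplies the Jukes–Cantor
transform $d = -\tfrac34\ln(1 - \tfrac{4p}{3})$, with a saturation error at
$p \ge 0.75$, and `cluster_subgenomes()` cuts an average-linkage tree at
two clusters, labelling chromosomes by majority family membership (ties are
flagged, not guessed; which cluster is called "K" needs an external anchor
and is accepted as an argument).

## Ploidy from allele balance

The classifier statistic is the fraction of heterozygous biallelic sites
with VAF in [0.48, 0.52], both ends inclusive; a library below 0.035 is
called octoploid, at or above it tetraploid. Usable sites are those with
total depth ≥ 8 and both alleles observed. We deliberately do *not*
restrict the profile to sites passing the binomial heterozygote test at
p = 0.5: at 60x depth that test rejects almost every VAF ≈ 0.25/0.75 site,
which would delete exactly the octoploid signal the band statistic needs.
A minimum of 500 usable sites is enforced (our own guard; the proportion is
unstable below that). Flow-cytometry bins are taken half-open
([40,80), [80,100), [100,140] thousand units) so the shared endpoints in
their stated ranges resolve deterministically. `call_genotype_binomial()`
applies the coverage floor (depth ≥ 8), the alternate-count floor (< 4 is
hom-ref), and an exact two-sided binomial test at 0.5 (default α = 0.05,
configurable — the level is not a published quantity); high-tail rejections
are hom-alt, low-tail rejections are conservative no-calls.

## Population structure

`wc_fst()` computes the Weir–Cockerham (1984) variance components a, b, c
per site directly from the published formulas (vectorized across sites) and
combines sites as the ratio of sums $\sum a / \sum(a+b+c)$ — never a mean
of per-site ratios. The test suite checks it against an independently coded
mean-squares (ANOVA) route to 1e-6 on hundreds of small tables.

`select_aims()` runs the ancestry-informative-marker cascade: site quality
(MAF ≥ 0.05, missingness ≤ 0.05), at least one pairwise $F_{ST} > 0.4$
among the designated parental populations, then two greedy left-to-right LD
pruning stages (|r| < 0.9 in 10-SNP/1-kb windows, then |r| < 0.95 in
1,000-SNP/10-kb windows), with r computed within populations and the
maximum across populations governing. The dual window bound closes at
whichever limit is hit first.

`ld_decay()` bins dosage-correlation r² by pair distance (500-bp bins) and
fits the Hill–Weir expected decay by nonlinear least squares. "Decay
extent" needs a numeric definition of "the curve stabilizes"; we use the
smallest distance at which the fitted curve's absolute slope falls below 1%
of its initial value (configurable). r² is computed on dosages, not
haplotypes, matching the package's diploidized genotype model.

`dapc_classify()` chains PCA (top 10 PCs), k-means (stated k), and linear
discriminant axes. `ancestry_coefficients()` takes leading eigenvectors of
the centered kinship and solves least-squares barycentric coordinates
against population vertices (centroids of designated non-admixed samples),
clipping to [0,1] and renormalizing — the projection step is our own
concrete choice for an otherwise under-specified "post hoc" simplex
mapping.

## Cross-coalescence divergence rule

`detect_separation()` walks the RCCR series past to present. A candidate is
a single declining step, a contiguous run of declining steps, or two
declining steps separated by one other step, with summed decline > 0.01;
the following step differences must stay ≤ 0.009 until the series end or
the next candidate; and when another qualifying decline begins within five
segments, the later one wins. The plateau condition is applied to step
*differences* (a rise is never disqualifying): the quoted observed range of
the "nearly zero" neighbours (−0.1 to 0.009) only makes sense for signed
differences. Smoothing is off by default (`smooth = 1`) and exposed as an
option. `scale_times()` converts scaled coalescent boundaries to
generations by dividing by the mutation rate (default 6.5e-8), and
`generations_to_years()` renders Ma to one decimal, ka to the nearest
integer.

## Local-ancestry HMM

The hidden state is the donor haplotype copy count $z \in \{0,1,2\}$ at
each site of one unphased sample. The stationary prior is
$\mathrm{Bin}(2, m)$. Per haplotype, the transition at genetic distance $d$
is the pulse-model kernel: stay with probability $e^{-gd}$, otherwise
re-draw from the stationary mix; the diploid 3×3 kernel is the two-haplotype
convolution. Emissions convolve $z$ Bernoulli draws at the donor frequency
with $2-z$ at the recipient frequency, both error-adjusted by
$f' = f(1-\varepsilon) + (1-f)\varepsilon$ with $\varepsilon = 0.001$ by
default. Forward–backward runs with per-site scaling (log-space totals), and
the forward and backward passes are required to agree on the total
log-likelihood to 1e-8 in tests.

Design departures, by choice: a single-pulse, two-ancestry model (the
multi-pulse, multi-source case is emulated by running the model per donor);
dosage emissions rather than haplotype emissions (no phasing anywhere in
the package); the effective population size enters only through the
maximum-generations bound (default 10,000 generations, Ne 100,000), not
through drift in the parental frequencies.

`decode_blocks()` hard-calls runs of sites with $P(z \ge 1) \ge 0.8$ (the
threshold is ours — the decoding rule is not published — and configurable),
merges runs across gaps shorter than 2 sites, drops runs shorter than 5
sites, and places boundaries midway between flanking sites (half-open
intervals, 0-based coordinates throughout the package).
`estimate_pulse()` profiles the cohort forward likelihood over a grid of
pulse ages, re-estimating the pulse proportion at each grid point as the
cohort's expected posterior donor fraction, warm-started along the grid.
`bin_blocks()` single-links blocks with reciprocal overlap ≥ 0.5 (the
"similarly positioned" criterion made concrete) and flags clusters carried
by ≥ 10 samples; `introgressed_fraction()` averages per-sample introgressed
base pairs over the genome size.

## Variance components and heritability

`van_raden_grm()` builds $W = M - 2\bar p$ from per-site mean-imputed
dosages and normalizes by $2\sum \bar p(1-\bar p)$. `reml_gq()` fits
$y = \mathbf{1}\mu + u + v + e$ with $\mathrm{Var}(u) = G\sigma^2_u$,
$\mathrm{Var}(v) = Q\sigma^2_v$, $\mathrm{Var}(e) = I\sigma^2_e$ by
average-information REML: scores use $\mathrm{tr}(PK_i)$ computed as
elementwise products (no matrix-matrix multiplies), updates are AI steps
with step-halving against the restricted likelihood and an always-uphill
EM-style fallback, and variances are constrained nonnegative with
boundary-aware flags. Standard errors come from the inverse AI matrix;
heritability shares $h^2_i = \sigma^2_i/\sigma^2_p$ carry delta-method SEs
and a full covariance so `h2_summary()` can test $h^2_v - h^2_u$ with a
two-sided Z. The random-effect design is the identity (one record per
genotype); replicate observations are averaged upstream.

`reml_partition()` fits all 18 chromosome kinships jointly and sums shares
per subgenome. Here the nonnegativity constraint is off by default: with
many small components, clipping at zero rectifies estimation noise and
biases *both* subgenome sums upward, which distorts their ratio;
unconstrained estimates cancel in sums, the standard practice for
chromosome-partition analyses. Per-chromosome estimates may therefore be
slightly negative; the subgenome sums and shares are the meaningful
quantities.

## Adaptation scan

`collapse_regions()` assigns peaks with log10 Bayes factor > 2 to fixed
20-kb tiling windows anchored at 0 — fixed tiling rather than
merge-of-overlapping because it is deterministic and O(1) per peak; the
anchoring convention is ours. `overlap_enrichment()` runs Fisher's exact
test over an *explicit* universe (never inferred silently), reporting the
conditional-MLE odds ratio with the sample odds ratio alongside.
`cluster_climate()` uses partitioning-around-medoids on the 1 − |r|
correlation distance (k = 7 by default) and picks per-cluster
representatives by maximum |correlation| with the cluster's first principal
eigenvector. `knn_impute()` fills missing phenotype cells from the k = 5
nearest samples on shared standardized traits. `rda_partition()` fits the
full redundancy analysis of the introgression carrier matrix on climate,
geography and kinship plus the three each-conditioned-on-the-other-two
partial models, with permutation tests (999 permutations by default)
permuting rows of the residualized predictors. `rda_outliers()` flags
loadings at least 2.5 sd from the mean on any retained axis (union across
axes — the per-axis-or-combined question is unstated, so the more sensitive
union is used and documented), reporting the implied two-tailed normal p,
$2(1-\Phi(2.5)) = 0.012$. `score_candidates()` admits genes overlapping an
introgression interval or whose midpoint lies within 10 kb of a peak, and
ranks by the weighted impact score $20\,\mathrm{high} + 5\,\mathrm{moderate}
+ 1\,\mathrm{low}$, then by midpoint distance.

## Numerical conventions and degenerate inputs

Positions are 0-based and intervals half-open everywhere. Monomorphic sites
are excluded (flagged) from F~ST~ and dropped from GRMs. Sites with fewer
than two genotyped samples in any population are excluded from F~ST~. The
HMM mandates scaled/log-space arithmetic and raises a numerical error on a
non-finite likelihood rather than returning garbage. Empty inputs raise
typed errors (`polyadapt_input_error`, `polyadapt_param_error`,
`polyadapt_data_error`) so callers can distinguish misuse from
insufficient data.

## Problem sizes used in the shipped checks

The package's property suites run at sizes chosen to make the statistical
claims meaningful on a single CPU: differentiation calibration at 3×100
samples and 5,000 sites over 10 seeds; pulse recovery at 40 samples, 500
sites/Morgan, 50 seeds; regional-heritability recovery at n = 500 with
5,000 sites (five genotype panels × ten phenotype draws); the subgenome
partition at n = 500, 18 chromosomes × 200 sites, 25 seeds; the
cross-coalescence rule on 200 noisy series. These sizes are the package's
own calibration choices and are documented here so that users scaling up
know the tested regime.

## Known limitations

The generators produce exchangeable (unlinked) sites, so LD-dependent
behaviour (AIM pruning efficacy on real LD, LD-decay extents) is exercised
only structurally. The ancestry HMM assumes known, drift-free parental
frequencies; with estimated frequencies its posteriors are overconfident.
The REML machinery supports only an intercept as fixed effect. Fisher
enrichments treat windows as exchangeable units, ignoring spatial
autocorrelation along chromosomes — the same caveat applies to the
published procedure it reimplements.
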