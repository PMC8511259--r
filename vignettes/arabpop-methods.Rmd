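---
title: "Models and design decisions in arabpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in arabpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its statistics: the models
each stage assumes, the tunable parameters with their defaults and units,
what the synthetic-data generator does and does not emulate, and the
design choices made where more than one defensible option existed. It
states no empirical result that the test suite does not itself compute.

## The synthetic world

Everything downstream is tested against cohorts drawn from an explicit
generative model, so it matters to be precise about what that model is.

**Autosomes.** K ancestral populations share a vector of ancestral allele
frequencies, by default Uniform(0.05, 0.95) — wide enough to populate
every allele-frequency bin while keeping sites informative. Population k
drifts away from the ancestor under the Balding–Nichols model: its
frequency at a site with ancestral frequency $p$ is

$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F_k)}{F_k},
\frac{(1-p)(1-F_k)}{F_k}\right),$$

so $\mathrm{E}[p_k] = p$ and $\mathrm{Var}[p_k] = F_k\,p(1-p)$; $F_k$ is
simultaneously the drift parameter and the expected FST to the ancestor,
and $F = 0$ is handled as the exact no-drift limit rather than a
degenerate Beta. Individuals receive ancestry proportions $q$ from a
per-group Dirichlet (or a fixed vector for unadmixed groups) and
genotypes $g_{ij} \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kj})$.
Sites live on a configurable synthetic genome (default two 50-Mb
chromosomes, 1-based VCF coordinates). Optional uniform Bernoulli
missingness exercises QC.

Two consequences worth keeping in mind. First, sites are independent
given the frequencies: there is **no linkage disequilibrium** (a stated
non-goal), so anything that in real data draws power from LD — notably
haplotype-based imputation — is structurally handicapped here (see the
imputation section). Second, the ratio-of-averages Hudson FST between
two populations drifted $F$ each satisfies
$\mathrm{E[num]}/\mathrm{E[den]} = 2Fp(1-p) / 2p(1-p) = F$ under this
model, which is the closed form the FST recovery tests use.

**Autozygosity.** `plant_roh()` overwrites genotypes inside
rejection-sampled, non-overlapping tracts with homozygous calls (the
allele drawn once per site from the individual's expected frequency) and
flips each call to heterozygous with probability `het_error` (≤ 0.05) to
mimic genotyping error. The tract registry is the ground truth for the
ROH caller benchmarks.

**The haploid locus.** `simulate_y_locus()` builds one ultrametric
pure-birth subtree per cluster with a specified TMRCA in years, joins
them at a root four times deeper (by default), and drops mutations on
each branch as Poisson(μ · L · branch-years) with μ = 0.76e-9 /site/yr
and L = 10 Mb by default. Every cluster stem is guaranteed at least one
mutation (forcing one, with a warning, if the Poisson draw is zero), so
each cluster owns private fixed SNVs with haploid cluster-vs-rest FST
exactly 1. Branch lengths of the exported tree are rescaled to realized
substitutions per site so that patristic distances agree with haplotype
differences, as they would on a maximum-likelihood tree; all supports
are 1.0.

**Determinism.** One top-level seed; each operation hashes
(seed, operation-tag) into its own substream, so any stage reproduces
bit-identically in isolation — VCF payload checksums are asserted equal
across reruns.

## Quality control

Sample-level: total missingness above 0.05 or any single chromosome's
missingness above 0.20 excludes a sample. The per-chromosome default is
a judgment call — the motivating failure mode is a sample whose one
chromosome is half missing, and 0.20 sits far above plausible batch
noise while catching that case; it is configurable. Outliers beyond 3 SD
on non-reference count, heterozygote count, or Ti/Tv are *flagged, not
excluded* (exclusion sits behind an explicit switch), because the action
taken on such samples is a cohort-level decision.

Variant-level, in fixed order (missingness → MAC → HWE → region) for
attribution, though the surviving set is order-independent: missingness
> 1%, minor allele count ≤ 2, exact Hardy–Weinberg p < 1e-5, BED
exclusion regions (0-based half-open; no default list is shipped).
Missing genotypes are excluded from MAC and HWE counts, not imputed.

The HWE test is the exact conditional (Levene–Haldane/Wigginton) test —
the two-sided p sums all heterozygote configurations no more probable
than the observed one — rather than a chi-square, because the 1e-5
threshold mostly bites at rare variants where the asymptotic test is
invalid. The implementation uses the standard probability recurrence;
the test suite checks it against an independent log-gamma enumeration
for every genotype table with n ≤ 50.

## Population structure

LD pruning is greedy and windowed (defaults r² > 0.2 in 50-SNP windows,
step 5 — the de-facto convention of the standard toolchain; only the r²
cutoff is a stated parameter of the emulated analysis). Within a window
the lower-MAF member of a correlated pair is dropped, ties to the later
position, deterministically; a brute-force all-pairs oracle fixes the
semantics in the tests. Monomorphic sites have undefined r² and are
never dropped for correlation.

PCA standardizes each polymorphic site by its estimated mean 2p̂ and SD
√(2p̂(1−p̂)) and eigendecomposes the sample covariance (via SVD). Missing
calls are mean-imputed per site — the standard choice for structure PCA,
avoiding case deletion. Signs follow the largest-magnitude-loading-
positive convention; eigenvalues sum to the total standardized variance
(asserted as a trace identity).

Dominant-ancestry assignment labels a sample with its argmax component
when the maximum fraction meets the threshold, default **≥ 0.5**. The
comparator is configurable because the emulated analysis is internally
inconsistent between "> 0.5" and "≥ 0.5"; the figure-caption convention
(≥) was chosen as describing what was actually produced. An exact tie at
the maximum is ADMIXED by rule. Raising the threshold can only shrink
labeled clusters (tested as a monotonicity property).

Allele sharing between cohorts A and B is *our operationalization* — the
fraction of sites segregating in A (non-reference allele seen at least
once) that also segregate in B, after site harmonization — because the
statistic it stands in for is not defined in enough detail to reproduce.
It is directional by construction and labeled as a stand-in in output
metadata.

## f-statistics

All f-statistics run on a site-frequency table (per population per site:
non-reference allele count and sampled allele count) and report a
weighted block-jackknife SE over contiguous genomic blocks (default 5
Mb), block weight = usable-site count, using the Busing delete-m
formula — the behavior of the standard admixture-statistics toolchain.
For ≤ 10 blocks the SE is asserted equal, to 1e-12, to an explicit
delete-one recomputation from the raw site table.

The f3 admixture form subtracts the finite-sample heterozygosity
correction $c(1-c)/(n_C-1)$ for the target only; no outgroup-f3 variant
is offered since only the admixture form is needed. A site is usable
when all three populations have ≥ 2 sampled alleles and the site is
polymorphic across the trio. Note the correction assumes C is sampled
independently of A and B: feeding the *same* sample as both C and A
yields $-\hat h_A/(n-1)$, slightly negative, by construction; the
"unadmixed target" null is an independently drifted population, for
which f3 ≥ 0 holds in expectation.

Patterson's D polarizes by the outgroup's major allele (sites with
outgroup minor-allele frequency above 0.01 are dropped) and is the
ratio of summed (w−x)(y−z) to summed (w+x−2wx)(y+z−2yz); positive D
means excess derived sharing between Y and W. Sites with zero
denominator are uninformative and excluded from the block tally.

FST: Hudson's estimator with unbiased within-population heterozygosity
terms is the default; the Weir–Cockerham option is the allele-level
ANOVA form, because the frequency-table interface carries allele counts
but not heterozygote counts. At equal sample sizes the two agree within
sampling noise (tested); per-site values are clipped to [−1, 1] for
reporting while raw numerators/denominators are retained, and the mean
is always the ratio of averages.

## Runs of homozygosity

The caller is a two-state HMM on hard genotype calls. Emissions: inside
an autozygous (AZ) tract a heterozygous call occurs with probability
`het_error` (default 0.001, absorbing genotyping error — the emulated
caller consumes genotype likelihoods, this pipeline sits downstream of
hard-call VCFs); homozygous calls split by the cohort allele frequency.
In the non-autozygous (HW) state emissions are Hardy–Weinberg at the
cohort frequency. Transitions integrate a two-state Markov process with
expected AZ tract 1 Mb and expected HW stretch 10 Mb (order-of-magnitude
typical for the emulated caller; both configurable) over the inter-site
distance. Segments are maximal runs with posterior P(AZ) > 0.5.

**Segment quality** is the mean of per-site Phred scores
−10·log10(1 − P(AZ)), capped at 100 per site, and segments with quality
≤ 50 are removed (strictly-greater retention). A plausible alternative —
Phred of one minus the *mean posterior* — was rejected because run-
boundary sites with posterior near 0.5 dominate that statistic and cap
it near Phred 30 regardless of how confident the interior is, which
would make a >50 threshold unsatisfiable; averaging per-site Phred
matches the per-site-quality convention of HMM-based callers and makes
the threshold discriminating. Marker density matters here: at WGS-like
spacing (~2.5 kb) true planted tracts score ≈ 55 and pass; at very
sparse spacing (~17 kb) even perfect tracts cannot exceed ≈ 40, which is
a genuine property of the evidence, not a bug.

Size classes: a 3-component Gaussian mixture is fitted by EM (multiple
restarts, unequal variances, degenerate fits restarted and ultimately
replaced by quantile boundaries with a diagnostic flag) on
**log10(length)** — whether the emulated analysis used raw or log
lengths is unstated; lengths span kb to tens of Mb, so the log scale is
the defensible choice. Components are ordered by mean and the class
boundaries are the points between adjacent means where the weighted
posterior responsibility flips (closed-form Gaussian crossing with a
grid fallback). Three components are fixed, not model-selected, because
three classes is part of the analysis definition. Populations with < 30
segments fall back to the pooled fit with a warning.

Inbreeding F is the method-of-moments excess homozygosity
(O − E)/(M − E) with E from plain cohort frequencies — deliberately not
leave-one-out — with the 2N/(2N−1) small-sample correction so that a
Hardy–Weinberg cohort centers on zero. Samples with < 100 usable sites
report NA. Gene overlap counts genes whose whole interval lies inside a
single segment ("complete overlap"), via a sorted sweep after 0/1-based
reconciliation.

## Y-chromosome sub-lineages

Input is a rooted tree with bootstrap supports and a haploid genotype
matrix. Edges with support < 0.9 are contracted into polytomies, the
removed edge's length added to its children, leaves untouched; missing
supports never collapse. "Genetic distance" for clustering is the
patristic (branch-length-sum) distance, matching the operation of the
cluster-picking tool the pipeline emulates; a clade is a cluster when
its maximum leaf-pair patristic distance is within the cutoff, maximal
clades only, ≥ 2 leaves.

The cutoff scan counts clusters of size > 10 at each grid point (default
grid spans 1e-5 to 4e-3 substitutions/site) and picks the maximizing
cutoff. Ties are broken **first toward the fewest singletons, then
toward the smaller cutoff**. The pure smaller-cutoff rule was tried
first and proved wrong in a characteristic way: the smallest tying
cutoff tends to sit exactly on a cluster's realized diameter, stranding
one boundary member as a singleton while the remaining 11/12 still count
as "large"; the stranded member then carries the stem SNVs outside the
cluster, so no site attains FST = 1 and the cluster loses its defining
set entirely. Minimizing singletons first removes that artifact without
changing the scan's objective.

Defining SNVs require haploid Hudson FST = 1 (within 1e-12) against all
remaining samples *and* within-cluster derived allele frequency 1, after
dropping singleton variants and sites with missingness > 1% (the
emulated analysis's filters). Sub-haplogroups with identical defining
sets are merged; clusters with empty sets yield none — both mechanisms
can reduce the haplogroup count below the cluster count, and both are
logged rather than asserted as the "real" mechanism.

Dating: t = S̄/(μL), with S̄ the mean per-member count of derived alleles
at cluster-private sites *since the clade MRCA* (cluster-private and
segregating; the fixed stem SNVs predate the MRCA and are excluded).
Singletons are **kept** in S̄ even though they are excluded from the FST
step: terminal-branch mutations are post-MRCA signal, and dropping them
biases the clock low by roughly the singleton fraction. Defaults
μ = 0.76e-9 /site/yr, L = 10 Mb, 30 yr/generation (used only when the
rate is per generation: t = S̄·g/(μ_gen·L)); all configurable, since the
emulated analysis does not print its constants. The 95% CI uses a
**Poisson bootstrap over sites**: writing S̄ = Σ_j f_j over private sites
with within-cluster frequencies f_j, the mutation events are independent
given the clade and their number is itself Poisson, so resampling each
site with Poisson(1) multiplicity reproduces the compound-Poisson
variance Σ f_j² exactly. A member-level bootstrap (also available) badly
undercovers, because member counts share tree branches and fixed-n
resampling misses the site-count randomness.

Group comparisons use the Mann–Whitney U: full enumeration of all
C(n, n₁) assignments with midranks for combined n ≤ 20 (identical
groups give p = 1 exactly, ties handled without approximation), and the
normal approximation with tie and continuity corrections above that;
the two modes agree within 0.01 at the boundary and the exact mode
matches `stats::wilcox.test` in its exact regime.

## Imputation evaluation

The saturation curve adds samples in random order, counting distinct
sites with a non-reference allele so far; the tail is summarized by a
least-squares fit of count against log(sample index) and the implied
growth per additional 100 samples.

The two imputers are deliberately minimal stand-ins so the evaluator can
be tested end to end: `freq` returns twice the panel allele frequency
(quality 0 by convention), `nearest_haplotype` copies the panel sample
minimizing the typed-site mismatch rate (quality = 1 − that rate).
Their quality scores are *not* comparable to external imputation-engine
r² metrics; the > 0.5 high-quality count is applied to whatever score
column is supplied.

Aggregate R² **pools** (truth, dosage) pairs across all variants and
samples in each allele-frequency bin — the semantics of the standard
concordance utility — rather than averaging per-variant R²; per-variant
values are emitted for diagnostics. Binning uses non-reference allele
frequency from the reference panel by default (what an analyst has
before seeing truth), with a truth-AF option for simulation studies.

Two honest caveats follow from the no-LD world. First, the freq
imputer's pooled R² is not exactly zero: within a bin the dosage still
varies *between* variants with the panel AF, so the pooled correlation
retains cor(g, 2·AF)² — about 0.1 in the widest default bin at test
scale, and exactly zero only per variant. The tests assert both facts
(every bin < 0.2; per-variant R² undefined for constant dosage) and
check the pooled value against a direct Pearson computation. Second,
nearest-haplotype copying cannot dominate the frequency dosage without
LD: copying one genotype squares the shrinkage factor of the attainable
correlation. Dominance is therefore tested where the stated world
supports it — a panel containing the target's own haplotypes, where
nearest-haplotype recovery is exact — together with the
panel-relatedness monotonicity property (an own-population panel beats a
diverged one).

## Pipeline

The orchestration layer is thin: a flat-key plain-text config (unknown
keys rejected before any compute, full config echoed into every output
directory), stages in fixed order, TSV artifacts per stage, a
machine-readable JSON run log, and stage failures that halt naming the
stage while retaining completed artifacts. Rerunning with the same seed
reproduces identical artifact checksums.

## What a green test suite does and does not establish

The generator covers the statistical structure the methods assume —
drifted frequencies, admixture, autozygous tracts, clustered haploid
genealogies, panel/target splits — with planted truth. It does not
emulate LD, coalescent recombination, sequencing reads, genotyping-error
structure beyond simple Bernoulli flips, or ancient-DNA artifacts.
Green tests therefore establish correctness of the estimators and the
pipeline plumbing on data satisfying the model assumptions, and
calibration (null Z distributions, CI coverage, FST recovery) at desk
scale; they do not validate conclusions about any real cohort, and
thresholds tuned to WGS-scale data (notably the Phred 50 segment
filter) interact with marker density as described above.
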