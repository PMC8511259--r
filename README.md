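# arabpop

Population-genomic analysis of whole-genome cohorts from admixed human
populations — quality control, population structure, formal admixture
statistics, autozygosity, Y-chromosome lineage structure and
imputation-panel evaluation — with a synthetic-cohort generator that
provides planted ground truth for every stage.

The package is aimed at statistical geneticists building or auditing a
cohort analysis pipeline of this shape: it re-implements the analytical
core of such a study as small, tested, composable functions, and every
claim the pipeline makes (an ROH call, an f3 Z-score, an imputation R²)
can be exercised against simulated data whose truth is known exactly.

## What is implemented

| Stage | Content |
|---|---|
| `synthdata` | Balding–Nichols ancestral model (per-population site frequency ~ Beta(p(1−F)/F, (1−p)(1−F)/F)), Dirichlet admixture, planted autozygous tracts, a haploid locus evolving on a simulated clustered phylogeny, reference/target panel splits. VCF/TSV/newick artifacts plus truth registries. |
| `qc` | Per-sample missingness (total and per chromosome), 3-SD outlier flags on count/het/TiTv metrics; exact conditional Hardy–Weinberg test; variant filters (missingness > 1%, MAC ≤ 2, HWE p < 1e-5, BED exclusion regions); multi-cohort site intersection. |
| `structure` | Greedy windowed LD pruning (r² > 0.2), genotype PCA (2p̂-centred, √(2p̂(1−p̂))-scaled), allele-sharing fractions, dominant-ancestry assignment from a Q matrix (max qᵢ ≥ 0.5, else `ADMIXED`). |
| `fstats` | f3(A,B;C) = mean[(c−a)(c−b)] − ĥ_C correction; Patterson's D on outgroup-polarized derived frequencies; Hudson and Weir–Cockerham FST as ratios of averages; weighted block jackknife (5-Mb blocks) for SE/Z; f3 admixture networks (f3 < 0, Z < −3). |
| `roh` | Two-state HMM (autozygous / Hardy–Weinberg) with distance-dependent transitions, posterior decoding, Phred > 50 segment filter; 3-component Gaussian mixture on log10(length) giving population-specific short/medium/long boundaries; method-of-moments inbreeding F; complete gene–ROH overlap. |
| `ylineage` | Bootstrap-support collapse (< 0.9), maximal-clade clustering under a patristic-distance cutoff, cutoff scan maximizing large (> 10) clusters, defining SNVs (haploid FST = 1, within-cluster AF = 1), Poznik-style lineage dating t = S̄/(μL) with bootstrap CIs, Mann–Whitney group comparisons. |
| `imputeval` | Variant-discovery saturation curves, pseudo-array masking, stand-in imputers (panel-frequency dosage; nearest-haplotype copy), aggregate R² pooled per allele-frequency bin ((0,0.001], (0.001,0.01], (0.01,0.1], (0.1,0.5], (0.5,1]). |
| `cli_and_config` | Flat-key plain-text config, end-to-end synthetic pipeline with echoed provenance and a JSON run log; `arabpop_cli()` entry point. |

## Worked example

```r
library(arabpop)

model <- ancestral_model(K = 2, n_sites = 20000, drift = c(0.2, 0.2),
                         seed = 42)
cohort <- simulate_admixed_cohort(model, list(
  SRC1 = list(n = 50, q = c(1, 0)),
  SRC2 = list(n = 50, q = c(0, 1)),
  ADMX = list(n = 50, alpha = c(20, 20))))

ft <- site_freq_table(cohort$genotypes)
fst <- fst_pairwise(ft, "SRC1", "SRC2")
cat(sprintf("Hudson FST (SRC1 vs SRC2): %.3f over %d sites\n",
            fst$fst, fst$n_sites))
f3_statistic(ft, "SRC1", "SRC2", "ADMX", block_size_bp = 5e6)
```

prints

```
Hudson FST (SRC1 vs SRC2): 0.198 over 19633 sites
f3(SRC1, SRC2, ADMX) = -0.0182567  SE 0.00023  Z -79.36  (20 blocks, 19710 sites)
```

Two populations drifted F = 0.2 from a common ancestor show a realized
ratio-of-averages Hudson FST of 0.198 (the Balding–Nichols expectation is
F itself), and the 50/50 admixed group is a strongly significant f3
target (f3 < 0, Z ≪ −3): its allele frequencies sit systematically
between the two sources, which no tree-like history can produce.

Dominant-ancestry assignment on the true admixture fractions, at a 0.6
threshold:

```r
asg <- assign_dominant_ancestry(q_matrix(cohort$true_Q), threshold = 0.6)
table(group = substr(asg$sample, 1, 4), label = asg$label)
```

```
      label
group  ADMIXED K1 K2
  ADMX      40  3  7
  SRC1       0 50  0
  SRC2       0  0 50
```

A Y-chromosome locus with four planted sub-lineages (TMRCA 12 kya,
μ = 0.76e-9 /site/yr over 10 Mb):

```r
yl <- simulate_y_locus(4, sizes = 12, depth_years = 12000, seed = 42)
sc <- scan_cutoffs(collapse_low_support(yl$tree), large_min = 10)
sh <- informative_snps(yl$haplotypes, sc$clusters$clusters)
ages <- date_lineages(sh, mu = yl$mu_per_site_year,
                      L = yl$region_len_bp, seed = 42)
print(ages[, c("id", "n_members", "n_defining", "s_bar", "age_years",
               "ci_lo", "ci_hi")], digits = 4)
```

```
   id n_members n_defining s_bar age_years ci_lo ci_hi
1 SH3        12        257 91.92     12094 10767 13498
2 SH1        12        286 83.83     11031  9737 12259
3 SH4        12        271 92.00     12105 10768 13509
4 SH2        12        308 93.42     12292 11052 13717
```

The scan recovers all four clusters, each defined by a few hundred
private fixed SNVs, and the estimated divergence times bracket the
simulated 12,000-year truth.

The full pipeline, end to end on synthetic data:

```r
run_pipeline(parse_config(overrides = list(seed = 7)), out_dir = "demo")
```

## Documentation

The methods vignette (`vignettes/arabpop-methods.Rmd`) describes the
statistical models, the synthetic world and its limits, and the design
decisions; function-level documentation is in the roxygen comments.
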