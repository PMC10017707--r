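# depscan

Chromatin-state screening of oncogene dependency from CUT&Tag profiles.

Tumor cell lines differ in how much their growth depends on a single
oncogenic transcriptional driver (the motivating system is Yap in
pancreatic ductal adenocarcinoma). `depscan` implements the analysis
chain that connects a quantitative dependency phenotype, measured by
cell-competition assays, to the chromatin landscape measured by CUT&Tag
across a panel of lines — and ships a synthetic-panel generator with
recorded ground truth so that every statistical claim is testable.

## What it computes

**Dependency score.** A driver-deleted (Tm+) and a driver-intact (GFP+)
population are mixed 50/50 and tracked by sequential FACS. Under
exponential growth the log2 odds is linear in time,

```
log2(N_test(t) / N_ref(t)) = const + (r_test − r_ref) · t ,
```

so the OLS slope estimates the log2 relative growth rate per day; the
dependency score is its negation. A PTF score (0–5) counts highly
expressed progenitor transcription factors (Sox2, Sox5, Twist2, Nr2f1,
Nr2f2) per line, grouped Low (0–2) / High (3–5).

**Cross-mark Kendall screen.** Per-antibody master peaks (union-merge of
per-sample calls) are filtered — detected in ≥ 3 samples, maximal
TMM-normalized count ≥ 10, overlapping the other mark — and each
retained locus pair is correlated (Kendall tau-b) against the per-line
dependency scores for both H3K27ac and BRD4. Loci with both taus > 0.3
are dependency-high, both < −0.3 dependency-low; discordant or weak
pairs are unlabeled. Rank-rank hypergeometric overlap (RRHO) and
Ward.D2 clustering summarize cross-mark concordance.

**Chromatin-state classification.** Master loci split into
H3K4me3± TSS/CRE and active/inactive (H3K27ac and BRD4 double
positivity), a seven-cluster partition (p1–p3 promoters, e1–e4
enhancers), combinatorial Jun/Sox2/Sox5/Twist2 co-binding categories,
Yap co-binding fractions, and ROSE-style super-enhancers (12.5 kb
stitching, rank-curve tangent cutoff).

**Footprints.** From per-base Tn5 insertion profiles around motif
sites: flank height (flanking accessibility over local background),
footprint depth (flank − core), relative depth (depth / flank height),
and bound/unbound calls from a two-component Gaussian mixture.

## Worked example

```r
library(depscan)

pan <- generate_panel(panel_config(n_loci = 1000, seed = 42))
#> synthetic_panel: 1000 loci x 19 lines; 100 planted loci; focal line line18

dep <- dependency_scores(pan$facs)
head(dep, 3)
#>   line_id log2_rel_growth standard_error yap_dependency n_timepoints
#> 1  line01      -0.9396990    0.005316677      0.9396990            4
#> 2  line02      -0.9586346    0.020906850      0.9586346            5
#> 3  line03      -0.2854724    0.005080994      0.2854724            5

nm1 <- normalize_counts(pan$counts$H3K27ac, tmm_factors(pan$counts$H3K27ac))
nm2 <- normalize_counts(pan$counts$Brd4,    tmm_factors(pan$counts$Brd4))
mt1 <- build_master_table(pan$peaks$H3K27ac, nm1, "H3K27ac")
mt2 <- build_master_table(pan$peaks$Brd4,    nm2, "Brd4")
pairs <- filter_for_screen(mt1, mt2)
scr <- dependency_screen(pairs, mt1, mt2,
                         setNames(dep$yap_dependency, dep$line_id))
table(scr$label)
#> YapD_H YapD_L   none
#>     49     48    287
```

The panel planted 50 loci whose signal rises with dependency and 50
whose signal falls (Kendall tau targeted at 0.6, negative-binomial
noise); the screen recovers 49 and 48 of them at the |tau| > 0.3
cutoff, with the labeled taus shown per locus:

```r
head(scr[scr$label == "YapD_H", 1:5], 3)
#>             k27ac_locus           brd4_locus tau_k27ac  tau_brd4  label
#> 14   chrS:799000-800000   chrS:799000-800000 0.6023392 0.5672515 YapD_H
#> 32 chrS:1660000-1661000 chrS:1660000-1661000 0.5555556 0.5789474 YapD_H
#> 36 chrS:1828000-1829000 chrS:1828000-1829000 0.5321637 0.3333333 YapD_H
```

Footprint metrics recover a planted 75% motif protection at 4-fold
flanking enrichment:

```r
sim <- simulate_insertion_profiles(protection = 0.75, n_sites = 2000,
                                   seed = 42)
footprint_metrics(aggregate_profile(sim$profiles, sim$strand),
                  motif_width = sim$motif_width)
#> flank_height 3.972, footprint_depth 2.975, relative_depth 0.749
```

`run_pipeline(run_config(input_dir, output_dir))` chains all stages on
a directory laid out by `write_panel()` and writes per-stage tables
plus a machine-readable `summary.json`. See the methods vignette
(`vignettes/methods.Rmd`) for the model, parameter meanings and design
decisions.

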