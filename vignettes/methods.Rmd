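---
title: "Methods: linking chromatin state to oncogene dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking chromatin state to oncogene dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscan)
```

# Overview

`depscan` quantifies how strongly a panel of tumor cell lines depends on
an oncogenic transcriptional driver (the motivating system is Yap in
pancreatic ductal adenocarcinoma lines profiled by CUT&Tag), and screens
the epigenome for the cis-regulatory elements whose activity tracks that
dependency. Five analysis stages are chained:

1. **Dependency scoring** from cell-competition assays.
2. **Between-sample normalization** of tag counts (binned TMM).
3. **A cross-mark Kendall screen** of per-locus signal against the
   dependency score, with concordance labels, RRHO and clustering.
4. **Chromatin-state and TF co-binding classification**, including
   ROSE-style super-enhancer stitching.
5. **Tn5-insertion footprint quantification** around motif sites.

A synthetic-panel generator with recorded ground truth exercises the
whole chain; every statistical guarantee stated below is checked by the
test suite on that generator, not asserted from real data.

# Dependency scoring

A test population (driver-deleted, e.g. Tm+Yap−) and a reference
population (driver-intact, GFP+Yap+) are mixed 50/50 and co-cultured;
FACS fractions are recorded every few days. Under exponential growth,

$$\log_2 \frac{N_\mathrm{test}(t)}{N_\mathrm{ref}(t)} =
  \log_2 \frac{N_\mathrm{test}(0)}{N_\mathrm{ref}(0)} + (r_\mathrm{test} - r_\mathrm{ref})\,t,$$

so the OLS slope of the log2 odds against time estimates the log2
relative growth rate per day. The *dependency score* is the negated
slope: lines whose driver-deleted population collapses fastest score
highest. Two conventions circulate for this kind of score (the slope
itself, or a monotone transform of endpoint fractions); we fix the OLS
slope because only the ranking matters downstream — the screen is a rank
statistic, invariant under any strictly monotone transform, and the test
suite asserts exactly that invariance.

Timepoints with a zero count in either channel are dropped rather than
pseudocounted: at the panel's cell numbers (~10^4 scored cells) a zero
indicates the population has left the dynamic range, and a pseudocount
would pull the slope toward an arbitrary constant. With fewer than two
usable timepoints the fit errors out.

The per-fit residual standard error is reported but under-covers
slightly (heteroscedastic binomial noise, 3 residual df at five
timepoints); the Monte-Carlo tests therefore assess the *estimator mean*
across replicates against the planted rate, which is the property that
matters for a 19-line panel.

PTF scores count how many of the five progenitor TFs (Sox2, Sox5,
Twist2, Nr2f1, Nr2f2) are "highly expressed" in a line. The underlying
calls in the motivating study are qualitative (western blot), so the
package exposes a single threshold: a factor is called when it reaches a
fraction `frac` (default 0.25) of the panel-wide maximum for that
factor and is strictly positive. Lines are grouped Low (scores 0–2)
versus High (3–5).

# Normalization

Scaling factors are estimated from counts in large genomic bins
(1250 bp for TF antibodies, 10,800 bp for histone marks and BRD4;
fragments above 800 bp are discarded), so the factor reflects
background coverage rather than peak signal. The factors themselves are
trimmed means of M-values (TMM): per-bin log2 ratios against a
reference sample, doubly trimmed (30% per tail on M, 5% per tail on
absolute intensity) and averaged with inverse delta-method-variance
weights. The trim fractions are the method's published defaults and are
exposed as arguments. The reference is the sample whose library-scaled
upper quartile sits at the panel median — a deterministic rule, so
factor computation is reproducible under sample relabeling. Factors are
rescaled to geometric mean 1 and turned into counts-per-million with
effective library sizes.

Normalization rescales whole columns, so it preserves within-sample
rank order; cross-sample ranks at a locus can move only when factor
errors exceed the margin between two lines' normalized counts. The test
suite checks factor accuracy against an independent implementation
(tolerance 0.02) and rank preservation directly.

# The cross-mark screen

Per-antibody **master loci** are the union-merge of all per-sample peak
calls (book-ended intervals merge; this is a merging convention, distinct
from annotation). A locus is *detected* in a sample iff it overlaps that
sample's own peak calls. Loci enter the screen when they are detected in
at least 3 samples, reach a maximal normalized count of at least 10
(the removal rule strikes counts strictly below 10), and overlap at
least one surviving locus of the other mark; cross-mark pairs use the
maximal-overlap partner, leftmost on ties.

For each paired locus, the Kendall tau-b (tie-corrected; normalized
counts can tie) of each mark's counts against the per-line dependency
scores is computed. A locus is labeled **dependency-high** when both
taus are strictly greater than +0.3, **dependency-low** when both are
strictly below −0.3, and unlabeled otherwise — including discordant
signs. We read the published cutoff as strict; at n = 19 the difference
between strict and inclusive is a measure-zero event for continuous
scores.

Concordance between the two marks' tau vectors is visualized by
rank-rank hypergeometric overlap: on a step lattice (default N/50), the
upper-tail hypergeometric p-value of the overlap of the two top-k sets.
Cells are exact tail sums (`phyper`), checked against direct summation
for small N. Heatmap ordering uses row-z-scored matrices, Euclidean
distances and Ward.D2 linkage, the same combination the field's heatmap
packages default to for this analysis.

# Chromatin states, TF combinations and super-enhancers

Master loci over all antibodies are split into TSS (H3K4me3-positive)
and CRE (H3K4me3-negative); *active* means H3K27ac- and BRD4-double
positive. Annotation overlap requires at least one shared base —
book-ended peaks do not annotate a locus, unlike the master merge. The
seven-cluster partition is: p1 (TSS, active, Jun+Sox2+), p2 (TSS,
active, Jun−Sox2+), p3 (all remaining TSS), e2/e3/e4 (CRE, H3K27ac−
BRD4−, with Jun+Sox2+ / Jun+Sox2− / Jun−Sox2+) and e1 (all remaining
CRE). The residual promoter/enhancer classes are defined by exclusion,
so the seven clusters provably partition the master set — a property
the suite asserts on 100 random fixtures. One reading note: the
inactive-class shorthand "H3K27ac|BRD4−" we interpret as *not
double-positive*, matching the activity definition used for the
active/inactive split.

TF combination categories over {Jun, Sox2, Sox5, Twist2} are assigned
by priority: all four; each exactly-three variant; the exclusive
"Sox5|Twist2+" class (exactly one of Sox5/Twist2 — a site bound by both
is excluded — together with one of Jun/Sox2); remaining two-TF pairs;
single TFs; none. The priority order makes the categories mutually
exclusive, so counts always partition each state class.

Super-enhancers are called ROSE-style: CRE loci whose gaps are at most
12.5 kb are stitched (the published default; no TSS-exclusion window,
since none was specified), stitched regions are ranked by total signal,
the rank–signal curve is scaled to the unit square, and the cutoff is
the signal at the first point where the discrete slope exceeds 1.
Regions at or above the cutoff are SE, the rest RE. The discrete rule
replaces the continuous tangent construction to make the cutoff
deterministic on finite data; on a heavy-tailed fixture (95 regions
near 1, 5 near 100) it flags exactly the 5, and on an all-equal or
sub-3-region input it flags none. SE signals are all at or above the
cutoff by construction; SE-min above RE-max is *not* implied (the
tangent is a global rule), and the tests only assert the former.

# Footprints

Around a motif of width *w* centered in a window, the profile is
divided into the core (the motif), two flanks (default 20 bp each,
immediately adjacent) and the local background (the outermost 50 bp on
each side). Heights are *ratios* over the background mean — the
published definition says "relative to the local background" without
fixing ratio versus difference; the ratio makes flank height
dimensionless and all derived metrics invariant to sequencing depth,
which is what allows comparison across antibodies. Then

- flank height = mean(flank)/mean(background),
- footprint depth = flank height − core height,
- relative depth = depth / flank height ∈ [0, 1] for non-negative
  signal.

Under the generator's three-tier Poisson model (background b, flanks
b·f, core b·f·(1−π)), the expected relative depth equals the planted
protection π, and recovery at π = 0.75 within ±0.05 at 2000 sites is an
acceptance test, as is strict monotonicity of the estimate across a
protection grid.

Bound/unbound calls fit one- and two-component Gaussian mixtures to
per-site depth scores and, when BIC prefers two components, call sites
with posterior > 0.5 for the higher-mean component bound; degenerate or
unimodal fits call everything unbound with a warning. This replaces the
internal scoring of external footprinting frameworks with a transparent
rule; only behavioral equivalence on planted data is claimed (≥ 95%
accuracy on a clearly bimodal mixture), not numerical equivalence to
any external tool. Bound + unbound = all, always.

A simplified k-mer (default hexamer) insertion-bias expectation is
provided: expected insertions at a position proportional to the
window-wide mean insertion count of the k-mer starting there, with the
corrected track rescaled to preserve total signal. It flattens a planted
hot k-mer but is deliberately first-order — no position-within-k-mer
effects, no dinucleotide interactions — and is optional in the
pipeline.

# The synthetic panel

`generate_panel()` emulates the study design on one synthetic contig:

- **19 lines** with dependency scores uniform on [0, 1] and the matched
  competition growth rate (−dependency, log2 units/day); a discrete PTF
  score 0–5 is derived by thresholding so that dependency and PTF score
  anti-correlate, mirroring the panel's structure.
- **Loci** (default widths 1 kb, 20 kb apart) with TSS fraction 0.3 and
  activity probabilities 0.44 (TSS) / 0.24 (CRE), the fractions
  observed in the profiled focal line; loci planted for the screen are
  always active, mirroring the real screen's active-in-the-panel
  precondition. Inactive loci carry mark signal reduced by a factor of
  10, so activity is reflected in the counts and hence in
  detection-based peak calls. Five clusters of three consecutive CRE
  loci sit 2 kb apart with 8× signal and full TF co-binding — the
  planted super-enhancers.
- **Counts** are negative binomial around mean curves. For planted
  loci, a Gaussian copula blends dependency ranks with noise at
  ρ = sin(πτ/2) (Greiner's relation), then a lognormal approximation of
  the count noise inflates ρ so that the *realized* Kendall correlation
  between counts and dependency targets `effect_tau`; a calibration
  test checks the realized tau against the target at the default
  configuration.
  Null loci are exchangeable across lines. At `dispersion = 0` counts
  equal the mean curve exactly: the noiseless limit must order planted
  loci perfectly by dependency, which Poisson sampling cannot
  guarantee, so dispersion zero means deterministic rather than
  Poisson.
- **Presence** is a detection threshold on counts, defaulting to the
  baseline mean so active null loci are detected in roughly half the
  samples. The focal line (lowest dependency, where TF profiling
  happens) has its mark peak calls pinned to the planted activity
  states, standing for deep profiling: this makes the emitted focal
  files exactly consistent with the recorded truth, which the
  classifier round-trip test requires.
- **TF co-binding** is drawn per locus with co-binding concentrated at
  active sites (40% of active sites carry all four TFs, versus 1% of
  inactive ones), and Yap binding enriched at co-bound sites — enough
  structure for the classifier's truth-table round trip without
  modeling motif sequence.

What the generator does **not** emulate: read-level artifacts
(duplicates, mappability), peak-call uncertainty (peaks coincide with
loci), inter-locus correlation beyond the planted SE clusters,
copy-number variation, and antibody efficiency differences beyond a
scalar factor. Passing tests therefore demonstrate the statistical
machinery — rank-screen calibration, partition identities, estimator
recovery — not robustness to those real-data pathologies.

# Numerical and design choices

- Intervals are 0-based half-open on disk (BED convention) and 1-based
  closed in memory (`GRanges` convention); conversion happens only in
  I/O.
- Merging treats book-ended intervals as one locus; annotation does
  not. The distinction is deliberate and documented at both call sites.
- Kendall tau is delegated to `stats::cor(method = "kendall")` (tau-b)
  after validity checks; an all-tied vector is an error, and a
  constant *count* row inside the screen is assigned tau 0 (a flat
  profile carries no rank evidence either way).
- The tau cutoff is strict (> 0.3), the count filter inclusive (≥ 10,
  because the removal rule strikes "< 10").
- Percent summaries round half-up, matching how printed percentages in
  figure panels behave (base R's round-half-to-even would disagree at
  e.g. 44.5).
- Problem sizes in the test suite: the screen-recovery check runs 200
  replicates of 5000-locus panels; null calibration runs 40 replicates
  of 1500 loci against a score-permutation oracle; the conservation
  suite runs 100 seeds of 80-locus panels. These sizes give
  Monte-Carlo error comfortably below the asserted margins.

# Limitations

- The screen's type-I behavior is calibrated for n = 19 lines; at other
  panel sizes the |tau| > 0.3 rule changes its null rate and should be
  re-examined with the permutation machinery shipped in the tests.
- TMM trims and the reference-sample rule are sensible defaults, not
  recovered constants; both are configurable.
- The footprint bias correction is a labeled simplification; profiles
  corrected by a full hexamer regression upstream can be supplied
  directly.
- The bound/unbound mixture rule assumes a reasonably bimodal depth
  distribution; heavily skewed unimodal data yields the conservative
  all-unbound answer.
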