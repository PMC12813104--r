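---
title: "Methods: benchmarking DNA-extraction kits on 16S OTU tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking DNA-extraction kits on 16S OTU tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitbench)
```

## Scope and assumptions

`kitbench` evaluates DNA-extraction kits *downstream* of read processing: its
inputs are an OTU count table (samples x OTUs), a six-rank taxonomy table, a
sample metadata/QC table and per-kit bench attributes. Everything upstream —
read trimming, denoising, OTU clustering, taxonomy assignment — is out of
scope and assumed done. The pipeline assumes a replicated design: several
technical replicates per species x kit combination and one no-input
("kitome") negative control per kit.

## The synthetic study generator

Because real kit-comparison data come from field samples with no known
ground truth, validation rests on a generator that plants every effect the
pipeline is supposed to detect.

**Community model.** Each host species carries a log-normal
relative-abundance profile (default log-sd 1.5), the simplest model
reproducing the long-tailed OTU distributions amplicon analyses assume.
Reads are drawn multinomially at a fixed depth, so observed relative
abundances are unbiased for the underlying proportions and converge as
depth grows.

**Chloroplast load** is a per-species parameter: red-algae-like hosts
default to 35% of read mass on chloroplast OTUs, brown- and green-algae-like
hosts to 8%, spread over a handful of OTUs whose order-level taxonomy is the
literal string `"Chloroplast"`. These defaults sit inside the ranges
reported for macroalgae hosts (up to ~40% for red algae, 5–10% otherwise).

**Kit effects.** Each kit applies (i) a systematic per-OTU log-normal
capture bias (one multiplier draw per species x kit, shared by all
replicates — that is what makes the bias detectable as a kit effect), (ii)
random OTU dropout, (iii) an optional chloroplast-affinity multiplier, and
(iv) reagent contamination: a shared contaminant profile (default 30 OTUs
with human-associated "-like" genus labels, disjoint from the community
label set) receives mass fraction `load / (load + template)`. This encodes
the dilution mechanism by which low-yield kits show proportionally more
reagent contamination. Kitome controls are drawn from the contaminant
profile alone, at a depth proportional to the kit's reagent load, so clean
kits produce shallow kitomes and high M/C ratios.

**QC table.** Concentration is template mass over the 60 µL elution volume
with multiplicative log-normal noise (sd 0.1), floored at the 0.1 ng/µL
fluorometric detection limit; input mass is uniform on 1.5–5 g; DIN and the
absorbance ratios get small Gaussian noise around per-kit means; one default
kit has `din = NA` to exercise the assay-failure path.

**Default kit panel.** The six default kits mirror the qualitative behaviour
of widely used commercial products: template yields 5–60 ng, reagent loads
0.5–1.5 ng, dilution factors 1–100, published simplicity scores and
per-sample costs, and chloroplast affinities spanning 0.7–1.3.
`chloroplast_affinity` deserves a note: with template dilution as the only
mechanism, a cleaner kit (smaller contaminant fraction *f*) necessarily
shows a *larger* chloroplast fraction `(1 - f) x base`, so the chloroplast
and contamination criteria would be mathematically opposed and no kit could
dominate both. Real kits differ in how much plastid DNA they co-extract;
the affinity multiplier models exactly that and makes the criterion
meaningfully rankable.

**Seeding.** The dataset RNG stream is split hierarchically by string-hashed
(species, kit, replicate) labels, so adding a kit or species never perturbs
the draws of existing ones, and the same seed reproduces the bundle
bit-for-bit.

**What the generator does not emulate:** sequencing error, chimeras,
PCR-cycle amplification bias, read-depth variation between samples,
compositional correlations between taxa, and cross-species OTU overlap.
Passing tests therefore demonstrate correctness of the downstream
arithmetic and decision rules under a clean statistical null, not robustness
to every artefact of real amplicon data.

## Contaminant calling

Published negative-control decontamination tools combine a
frequency-vs-concentration test and a prevalence test and flag an OTU when
either score crosses a threshold. `call_contaminants()` keeps that
interface — two scores, "either" combination, default threshold 0.3 — but
with deliberately simple, fully specified tests:

* **Prevalence score:** one-sided Fisher exact p-value that presence
  (count ≥ 1) is more likely in controls than in true samples. Small score
  = control-enriched = contaminant-like.
* **Frequency score:** permutation p-value (999 seeded permutations shared
  across OTUs) for negative Spearman correlation between relative abundance
  and sample DNA concentration. Constant-abundance OTUs get score 1.

Design choices worth recording:

* **Pooled controls by default.** Within one kit the template mass is
  roughly constant, so a kit-matched frequency test has no concentration
  gradient to exploit; pooling all kits' samples provides one. A
  `per_kit = TRUE` mode tests each kit against its own control and unions
  the flags.
* **Presence = count ≥ 1, no rarefaction.** The simplest defensible rule;
  rarefaction before prevalence testing is deliberately not performed.
* **Null behaviour.** Under a null with no contamination gradient, the
  frequency score is a uniform permutation p-value, so about `threshold` of
  OTUs are expected to be flagged; the prevalence score is nearly always 1
  at saturating depth. The false-positive control in the test suite bounds
  the flagged fraction at `threshold x 1.2` averaged over 20 simulations.

Note that per-sample contamination *levels* used in ranking are computed
from the called set, so false positives inflate all kits roughly equally;
rankings depend on the relative differences, which the planted
template-dilution mechanism dominates.

## Community metrics

Bray–Curtis dissimilarities are computed on raw counts (the replicated
design keeps depths comparable; optional rarefaction was considered and
rejected as an extra stochastic layer). PCoA is classical metric scaling;
axes with negative eigenvalues — expected for Bray–Curtis — are reported
and dropped. PERMANOVA permutes labels freely (no strata), matching a
single-factor design, and uses the standard `(1 + more-extreme) / (1 +
n_perm)` p-value so p is never zero. The implementation is vectorised over
group-index lists (needed to run 500 calibration datasets briskly) and is
cross-checked against `vegan::adonis2` in the tests.

Reproducibility uses intersection-over-union of presence sets across a
kit's replicates: the union denominator treats "detected by this kit at
all" as the reference set. A `denominator = "total"` option (all OTU
columns) is provided; presence is 1 read, configurable upstream of the
call. A replicate with zero detected OTUs yields rate 0 with a warning
rather than an error, since empty replicates are a legitimate (bad) kit
outcome.

## Ranking rules

All rules emit integer ranks with minimum-rank ties and skipping (1, 1, 3):
since aggregate ranks are plain sums, tied kits must carry equal weight and
the next kit must resume at its sorted position.

* **Mean ranking** (yield, DIN, Shannon, chloroplast, simplicity, cost):
  rank by mean replicate value, direction per criterion. Kits whose assay
  failed outright (all values missing, e.g. unmeasurable DIN) are excluded
  from the comparison and imputed one rank below the worst measured kit,
  with a note in the output — failing the assay is information, not missing
  data.
* **Contamination rule:** kits below 1% in *all* replicates share rank 1;
  the rest are ranked by ascending mean starting after the qualifying
  block. The strict `< 1%` reading is used; a replicate exactly at the
  threshold disqualifies.
* **Six-equal-bin rule** (reproducibility): the min–max range is split into
  six equal bins computed species-by-species; bins are half-open from below
  with the top bin closed, the best bin maps to rank 1, and empty bins
  still consume rank numbers. Bin membership is evaluated against
  explicitly computed boundaries (`findInterval`), which keeps values that
  sit exactly on a boundary in the upper bin regardless of floating-point
  rounding. A degenerate range puts every kit at rank 1.
* **Dilution rule:** factors ordered 1 < 10 < 100 < failed, with `failed`
  strictly worst — DNA that never amplifies is a worse inhibition outcome
  than any finite dilution. Replicates are summarised by their worst
  (largest) factor.

The Total rank sums all nine criteria; the Quality rank drops simplicity
and cost. No weighting or rank-aggregation optimisation is applied — plain
summation is the method being implemented. The criterion set is assembled
explicitly in `kit_benchmark()`, so custom panels can be built by calling
the rule functions and `aggregate_ranks()` directly.

## Numerical and validation choices

Problem sizes in the test suite and acceptance script were chosen to make
the statistical checks informative at desk scale: PERMANOVA type-I
calibration uses 500 null datasets of 6 groups x 3 samples at 999
permutations; contaminant recall and false-positive control use 20
simulated studies at 50,000 reads per sample; planted-dominance recovery
uses 20 studies at 4,000 reads; the mixing rule is checked at depth 10^6
where the multinomial standard error is far below the 1% tolerance. The
planted-dominance panel gives one kit strictly best values on all nine
criteria; with eight criteria won strictly (rank 1 vs ≥ 2), the winner's
rank sum beats any competitor even in the worst reproducibility-bin
outcome, so recovery is a sharp correctness check rather than a
probabilistic one.

## Limitations

Chloroplast filtering relies on exact order-level labels; taxonomy dialects
that tag plastids differently must be normalised on input. The contaminant
caller is a stand-in with the same interface as established tools, not a
reimplementation of any of them; on real data with batch structure or
cross-contamination it will be conservative at best. Rankings are ordinal
summaries — a kit one rank better may be negligibly different in value, and
the criterion panel treats all criteria as equally important by
construction.
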