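---
title: "Methods: junction-based differential splicing in an RNAi screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-based differential splicing in an RNAi screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`splicescreen` analyzes an RNAi depletion screen read out by RNA-seq at the
level of splice-junction counts. The design it assumes: each of ~56
candidate splicing regulators is depleted in two biological replicates,
plus one untreated library; junction counts per library arrive as BED
files (interval = the intron, score = read count), together with an exon
annotation carrying first/last-exon and CAGE-support flags. The pipeline
classifies alternative-splicing events, quantifies percent spliced in
(Ψ), synthesizes a virtual reference per event, and calls differential
splicing per knockdown, followed by network-level statistics.

### Coordinates and naming conventions

All coordinates are BED-style 0-based half-open; a junction's interval is
the intron. The `donor` and `acceptor` fields of a junction record are
*positional* (genomic left and right); on the minus strand the biological
donor (5′ splice site) is the genomic-right end. Event names follow
transcript coordinates: junctions sharing their genomic-right end with
differing left ends are an A5SS (alternative donors) on the plus strand
but an A3SS on the minus strand, where the genomic-left shared point is
the acceptor. Junctions of unknown strand are admitted to SE, CSE, MXE,
A5SS, A3SS and RI discovery (named by the plus-strand convention) but
never to AFE/ALE, which are inherently strand-dependent. Junction equality
ignores the BED name field.

### Event classification rules

Discovery proceeds in a fixed precedence order; each rule consumes
junction patterns and exact exon-boundary matches:

* **SE** — a skip junction (d0, a2) together with junctions (d0, a1) and
  (d1, a2) and an annotated exon exactly spanning [a1, d1). Inclusion
  isoform = the two flanking junctions (length 2); exclusion = the skip
  junction (length 1).
* **CSE** — the same pattern where the skipped interval is realized by a
  chain of two or more exons connected by internal junctions; the
  inclusion isoform holds the whole chain.
* **MXE** — two or more single-exon paths sharing the outer donor and
  acceptor, with pairwise-distinct in/out junctions, no direct outer
  junction, and no junction connecting the candidate internal exons.
  Requiring distinct junctions per path matters: two exon variants that
  share their start and are reached through one common upstream junction
  are an alternative splice site, not mutually exclusive exons, and
  without this requirement they would be misclassified. Overlapping
  internal exons are accepted as mutually exclusive (they can never be
  spliced together).
* **A5SS / A3SS** — two or more junctions sharing one end. The varying
  splice site must abut an annotated exon boundary, except when the
  alternative junction itself carries secondary-annotation status (the
  external evidence substitutes for the exon). Shared-end groups whose
  varying ends abut two or more flagged first/last exons are reserved for
  AFE/ALE discovery, and groups containing a junction already claimed by
  an SE/CSE/MXE event are skipped — this precedence keeps the flanking
  junctions of a cassette exon from being double-reported as alternative
  splice sites.
* **AFE / ALE** — two or more annotated first (or last) exons of a gene
  joined by junctions to a common downstream (upstream) point; one isoform
  per terminal exon. First exons must additionally be CAGE-supported
  (configurable, `require_cage`), because an apparent alternative first
  exon without independent transcription-start evidence is more likely an
  incomplete transcript model.
* **RI** — a junction whose intron interval is strictly contained within a
  single annotated exon (the single-exon form of the unspliced
  transcript). Intron-body read counts may be supplied as an optional
  region-count table; annotation containment is the default evidence rule
  since junction data alone cannot distinguish retention from background.

Annotated-but-unexpressed junctions are first merged into the universe
when they share exactly one end with an expressed junction: such a
junction certifies that the expressed junction can be alternatively
spliced even if the alternative form is absent from these libraries.
Novel junctions pass an upstream filter requiring read-start offset
entropy ≥ 2 bits (a stack of reads at a single alignment offset is the
signature of a mapping artifact) and ≥ 2 reads; both thresholds are
configuration keys, since no canonical values exist.

Gene assignment is by maximal overlap between the event span and each
gene's exon span; ties are ambiguous and excluded (logged).

### Quantification

Isoform read counts are sums over the isoform's junctions (plus region
counts for retained introns); junctions shared by two isoforms of one
event are ambiguous and counted for neither. Abundance is count divided by
isoform length, and

Ψ = a_incl / (a_incl + a_excl).

**Isoform length units** are the package's most consequential assumption:
length = number of junctions in the isoform (retained-intron exclusion
isoforms: intron length / read length, floored, minimum 1). Each junction
offers one read-sampling opportunity of equal width, so dividing by the
junction count equalizes sampling opportunity and reproduces the expected
2-vs-1 count asymmetry of a cassette exon at Ψ = 0.5. When both abundances
are zero, Ψ is undefined (NA), which is distinct from 0.

Replicates are **pooled by summing counts per condition** before Ψ,
reference construction and testing: the test consumes one count pair per
knockdown, and pooling is the minimal reading consistent with that. A
`per-replicate` mode computes calls per replicate and intersects them, as
a sensitivity analysis. An (event, sample) pair is testable iff inclusion
+ exclusion counts reach 20 reads (inclusive).

### Virtual reference and testing

Per event, over all RNAi conditions whose row is testable (the untreated
library is excluded, and at least 3 contributing conditions are required):
median total count × median per-isoform count ratio gives the reference
counts. For two isoforms the median inclusion and exclusion ratios sum to
one exactly; for more isoforms the medians are renormalized. Even-sized
medians use the mean of the central pair. Reference counts are rounded
half-up to integers for the exact test only; ΔΨ uses the real-valued
reference. ΔΨ = 100 × (Ψ_sample − Ψ_reference) in percentage points.

The two-sided Fisher's exact test is computed in-package by log-space
hypergeometric summation (all tables with the observed margins whose
probability is at most the observed table's, within relative tolerance
1e-7); a zero margin returns p = 1, and when the whole support qualifies
the p-value is exactly 1. Benjamini-Hochberg correction is applied per
(condition, event type). Multi-isoform events contribute one candidate
test per isoform (that isoform against the pooled rest, lengths summed)
to the same correction group, and the isoform with the lowest corrected
p-value is reported, ties broken by larger |ΔΨ| then lower isoform index.

A call is significant iff corrected p < `fdr` (default 0.05) **and**
|ΔΨ| > `dpsi_min` (default 10 points, strict). Magnitude tiers are weak
(10, 25], moderate (25, 50], strong (50, 100] — boundary values fall in
the lower tier, an explicit choice where the printed ranges overlap.
Direction: ΔΨ < 0 means the depleted protein activated inclusion, ΔΨ > 0
that it repressed it. The untreated condition is reported descriptively
and never tested against the reference.

### Network statistics

* **Bias** (cassette-exon calls per protein): two-sided exact binomial
  test of activated vs. repressed counts at p₀ = 0.5, by the
  point-probability convention (summing point probabilities not exceeding
  the observed one) — documented because the doubling convention differs
  on asymmetric counts. Bonferroni over proteins with ≥ 1 call; labels
  only at the corrected threshold.
* **Pairs**: for each protein pair, the universe is the set of events
  jointly testable in both conditions (not all discovered events — using
  all events would inflate enrichment through differential
  expressibility). The 2×2 affected-by-A × affected-by-B table gives a
  two-sided Fisher p, Bonferroni over pairs with non-empty universe.
  Shared affected events split into coordinated (same ΔΨ sign) and
  antagonistic; majority labels the pair, ties are mixed.
* **Cross-regulation**: significant calls landing on the assayed
  regulators' own genes, restricted by default to moderate/strong
  magnitude; self-targeting is excluded from the matrix and reported
  separately. The matrix is a pure function of the calls table.
* **TF targets**: peak-covered bases within the strand-oriented window
  [TSS − 2000, TSS + 100]; genes above the 90th percentile of nonzero
  scores are targets. The score formula and cutoff are quantile-based
  stand-ins, exposed in the configuration, since no canonical values
  exist.

## The synthetic-data generator

The generator is the package's test bed and defines its study conditions:
~56 proteins × 2 replicates + 1 untreated library; one event per synthetic
gene on chromosomes `chrS1…`, with geometries whose junction ends coincide
exactly with exon boundaries; AFE/ALE genes alternate strands to exercise
the strand logic, every third AFE gene carries three first exons to
exercise multi-isoform testing. Baseline inclusion Ψ is uniform on
[0.2, 0.8] (kept away from the boundaries so planted shifts of every tier
remain representable). Planted effect magnitudes follow the tier mix
weak : moderate : strong = 0.55 : 0.42 : 0.03, matching the observation
that strong changes are rare; each protein receives
`targets_per_protein` (default 20) random target events. Coregulated
pairs share a configured fraction of one protein's cassette-exon targets
with matched (coordinated) or opposed (antagonistic) signs; cross-links
plant an effect on the target protein's own gene.

Counting noise: the total event count per library is Poisson around
`depth_per_event`; the inclusion/exclusion split is beta-binomial (two
isoforms) or Dirichlet-multinomial (more) with overdispersion ρ
(default 0.01, a free parameter — replicate-to-replicate Ψ variance is
not constrained by external data). The success probability is the
*length-weighted* count probability q = Ψ·L_incl / (Ψ·L_incl +
(1−Ψ)·L_excl), so that the abundance-normalized Ψ̂ is a consistent
estimator of the planted Ψ. Reads within an isoform are split uniformly
across its junctions; retained-intron isoforms deposit reads as region
counts. Knockdowns affect only their planted events — no global
transcriptome shift, no NMD degradation, no alignment artifacts, no
gene-expression changes are simulated. Passing recovery tests therefore
demonstrates correctness of the statistical machinery under the model's
own assumptions, not robustness to the full complexity of real RNA-seq
(mappability, overlapping genes, annotation errors, correlated secondary
effects).

## Numerical and degenerate-input choices

* Reference counts are rounded *half-up* (`floor(x + 0.5)`), not by R's
  banker's rounding, for determinism.
* Duplicate junction BED lines merge by summing counts, with a warning.
* Events testable in fewer than 3 RNAi conditions get no reference and are
  untestable; an all-identical count matrix is a fixed point (ΔΨ ≡ 0,
  p ≡ 1, no calls).
* Determinism: a single seed drives model generation, and a derived seed
  the count simulation; the analysis pipeline itself uses no randomness,
  so identical inputs re-run byte-identically.
* Derived seeds stay below 2^31.

## Validation problem sizes

The test suite validates discovery exactness on 200-gene screens with all
eight types across ten seeds; Fisher p-values against exhaustive
enumeration for all 2×2 tables with margins ≤ 25; BH against an
independent step-up reimplementation on 1000 random vectors; the null
false-call rate on 2000 events × 20 conditions (dispersion 0.01, pooled
depth 200) across five seeds; and power for 30-point planted shifts at
the same depth. Cross-regulation recovery is checked at depth 500 and
dispersion 0.002, where measured magnitude tiers reflect planted ones
(at screen-default noise a planted weak effect can straddle the
weak/moderate boundary). The acceptance script's demonstration screen
uses 300 events × 56 proteins with 8 targets per protein — a scaled-down
design in which roughly the same per-protein call counts arise
proportionally as in a full-size screen.

## Known limitations

* Ψ̂ carries irreducible binomial sampling noise: at pooled depth n its
  standard error is ≈ sqrt(Ψ(1−Ψ)/n) (0.011 at n = 2000, Ψ = 0.5), so
  tight per-pair recovery (e.g. ±0.02 for 99% of pairs) requires depths of
  several thousand reads per event.
* The classifier assumes junction ends coincide exactly with annotated
  exon boundaries; soft-clipped or mis-annotated boundaries would require
  a tolerance the package does not currently implement.
* The virtual reference assumes most conditions leave an event
  unperturbed; screens where a majority of knockdowns shift the same event
  bias the medians toward the perturbed state.
* Fisher's exact test treats pooled counts as one sample and does not
  model biological replicate variance; the `per-replicate` intersection
  mode is a conservative workaround, not a replicate-aware model.
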