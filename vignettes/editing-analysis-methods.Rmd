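---
title: "Methods: quantifying and classifying A-to-I editing with editomekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and classifying A-to-I editing with editomekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomekit)
```

## The measurement model

A-to-I editing deaminates adenosine to inosine within double-stranded RNA;
sequencers read inosine as guanosine. In a stranded RNA-seq library a
plus-strand editing site therefore appears in the forward-strand pileup as G
reads among A reads, and a minus-strand site as C reads among T reads.
`editomekit` consumes per-site, per-sample pileup base counts (one row per
site × sample, counts always on the forward reference strand) and derives
strand-aware `(edited, total)` pairs, where

* plus strand: edited = G count, reference = A count;
* minus strand: edited = C count, reference = T count;
* **total = edited + reference only.** Bases unrelated to the A-to-I signal
  (e.g. C or T reads at a plus-strand site) are excluded from the
  denominator so sequencing noise at other bases cannot dilute the editing
  rate. This is a deliberate choice: editing tools differ on the
  denominator, and keeping only informative reads isolates the signal the
  analysis is about.

### Pooled genotype rates and filters

The per-genotype editing rate pools replicates by **summation before
division**: `rate = sum(edited) / sum(total)` across the (by default three)
replicates. This is the depth-weighted estimate; the unweighted mean of
per-replicate rates is a different (and worse) estimator, and the test suite
contains an explicit counterexample separating the two.

Sites enter downstream analysis (the "considered" set) when

* the pooled depth is at least `min_depth` (default 50) in **every**
  genotype of the comparison, and
* the pooled rate is at least `min_rate` (default 0.01) in **each** control
  genotype (WT and the double-heterozygous control).

All thresholds are inclusive ("≥") at the boundary. The depth rule is
applied per genotype on the pooled counts: the phrase "combined read
coverage" in study descriptions of this design is ambiguous between
per-replicate and pooled-per-genotype, and the pooled reading both matches
the word "combined" and makes the filter meaningful under overdispersed
coverage.

### Differential editing

Between two genotypes with pooled counts `(e_a, n_a)` and `(e_b, n_b)` the
package computes the pooled two-proportion statistic

```
phat = (e_a + e_b) / (n_a + n_b)
z    = (r_a - r_b) / sqrt(phat (1 - phat) (1/n_a + 1/n_b))
```

with `z = 0` when `phat` is degenerate (0 or 1: no informative evidence
either way) and no call when either side has zero depth. A call is
significant when `|z| >= z_threshold` (default 5) and both genotypes pass
the depth filter. Dirichlet-multinomial editing callers also report a
"z"-style score at this threshold; our statistic is an explicit, documented
two-proportion stand-in, and numerical agreement with those tools is not
claimed.

### ADAR specificity classification

The control level of a site is the **unweighted mean** of the WT and
double-het pooled rates — "the average editing rate of the two control
genotypes" reads as a mean of two levels, not a re-pooling of their counts
(re-pooling would silently weight the control with the deeper libraries).
Relative rates are `rel_a1` (ADAR1 editing-dead / control) and `rel_a2`
(ADAR2 knockout / control). With lost threshold `L = 0.10` and inhibits
threshold `H = 1.50`:

| label | rule |
|---|---|
| SHARED | `rel_a1` and `rel_a2` both in the **open** interval (L, H) |
| ADAR1_SPECIFIC | `rel_a1 < L`, `rel_a2` in the **closed** interval [L, H] |
| ADAR1_SPECIFIC_ADAR2_INHIBITS | `rel_a1 < L`, `rel_a2 > H` |
| ADAR2_SPECIFIC / ..._ADAR1_INHIBITS | mirror images |
| NEITHER_RETAINED | both `< L` |
| UNCLASSIFIED | anything else |

"Unchanged" editing has no universally agreed numeric bounds; we fix it as
the closed interval `[L, H]`, use the open interval for SHARED, and make
every boundary case deterministic (a relative rate exactly at `L` is neither
lost nor shared, hence UNCLASSIFIED). `NEITHER_RETAINED` and `UNCLASSIFIED`
are our additions for patterns that match no rule; a partition property test
guarantees every considered site receives exactly one label.

### Hyperediting

A site is hyperedited when some 100-bp window (`hyper_window`) containing it
holds at least 10 sites (`hyper_min_sites`). The window span is inclusive:
positions `p .. p + 99` lie "within 100 bp", so the first and last site of a
qualifying window differ by at most `hyper_window - 1`. Definitions of this
kind appear both as "more than 10" and "10 or more" in the literature on
this design; we adopt **≥ 10** as the default and leave the count
configurable. Detection is an O(n) two-pointer sweep per chromosome;
qualifying windows whose member-site ranges overlap are chained into maximal
regions. The sweep is verified against a brute-force oracle that enumerates
every window, on hundreds of randomized instances plus the boundary
fixtures (10 sites spanning 91 bp form a region; 9 sites do not).

### Annotation and sequence context

Gene parts are assigned with fixed precedence promoter > 3′UTR > exon >
intron > intergenic, ties within a level broken by the smallest interval
(then interval order, for determinism). The delegating annotation tools used
in published analyses of this design do not state their tie-breaking; ours
is explicit and configurable. Promoters default to 1,000 bp upstream through
200 bp downstream of the TSS. Repeat families collapse labels beginning
"B1"/"B2" to the murine SINE families with precedence B1 > B2 > other.

Sequence context matrices report per-position A/C/G/T frequencies in a
±`context_flank` nt window (default ±5; logo widths in published figures are
not stated numerically). Minus-strand windows are reverse-complemented so
the edited base reads A at position 0; sites whose strand-adjusted center is
not A are excluded with a warning and counted, as are sites too close to a
contig edge. On validated sites the center column is pure A and every row
sums to 1.

## The synthetic study

The simulator emulates the five-genotype (WT, double-het control, ADAR1
editing-dead, ADAR2 knockout, compound double mutant) × three-replicate
whole-brain design at **pileup level** — every downstream computation
consumes counts, so read-level simulation would add cost without adding
validation power.

* **Genome**: i.i.d. uniform ACGT chromosomes (default 2 × 100 kb), with
  non-overlapping 100-bp cluster regions labeled alternately "B1-like" /
  "B2-like" standing in for SINE repeats.
* **Editome**: site-selective sites at A/T reference positions outside
  clusters (T positions become minus-strand sites), plus ≥ 10 sites planted
  inside each cluster so clusters qualify as hyperedited. Each site draws a
  class from `class_mixture` (default: 50% shared, 15% ADAR1-specific, 25%
  ADAR2-specific, 5% each inhibits variant — reflecting a brain editome in
  which roughly half the sites are shared and ADAR2 accounts for more
  specific sites than ADAR1) and a control rate uniform in
  `control_rate_range` (default [0.05, 0.70]).
* **Class-legal rates**: WT and double-het equal the control rate; the
  double mutant is exactly 0 (editing requires a catalytically active ADAR);
  the single-mutant rates are control × a multiplier drawn uniformly from
  the class's legal range ("lost" < 0.10, "unchanged" [0.10, 1.50],
  "inhibits" (1.50, 3.00]), kept `boundary_margin` (default 0.02) away from
  the 0.10/1.50 thresholds so planted classes are recoverable rather than
  coin flips at the boundary. Because a rate cannot exceed 1, multiplier
  upper bounds are capped at `0.99 / control`, and for the inhibits classes
  the control rate itself is truncated to keep the legal interval non-empty
  (control ≤ 0.99/(1.5 + 2·margin) ≈ 0.64). This truncation is a legality
  constraint of the generative model, not a tuning knob.
* **Counts**: per site × genotype × replicate, depth ~ NegBinom(mean
  `coverage_mean` = 200, dispersion 0.3; variance μ + 0.3 μ²), floored at 1;
  edited reads ~ Binomial(depth, true rate); every read independently
  corrupted to a uniformly chosen other base with probability `error_rate`
  (default 0.001). The negative binomial (rather than Poisson) makes the
  ≥ 50 depth filter genuinely informative, and the error floor gives the
  double-mutant null and the non-edited-base sanity checks something real to
  reject. Real studies of this design use actual reads and publish no noise
  model; all noise parameters here are the package's own and are documented
  as such.
* **Determinism**: each stage seeds the RNG from `seed` plus a fixed
  offset; identical configurations give byte-identical FASTA/BED/TSV
  outputs, which the run manifest's per-file checksums make checkable.
* **Conserved flags**: real analyses use an externally curated
  evolutionarily conserved site list; the simulator instead marks a
  configurable fraction (default 5%) of non-cluster sites as conserved.
  This is synthetic provenance, present so the conserved-summary path is
  exercised, and is labeled as such.

### What the estimator estimates (and the rate-recovery check)

Under the error model, a read at a site with true editing rate `p` is
observed as the edited base with probability `p(1−e) + (1−p)e/3` and as the
reference base with probability `(1−p)(1−e) + pe/3`; conditioning on the
informative (reference + edited) reads, the observed edited count is exactly
Binomial(n, `p_obs`) with

```
p_obs = (p (1 - e) + (1 - p) e / 3) / (1 - 2 e / 3)
```

(`expected_observed_rate()`). The rate-recovery property therefore checks
pooled counts against exact 99% binomial intervals at `p_obs`: that is the
estimator's actual estimand under the generator. The distinction only
matters at `p = 0`, where the interval at the raw rate is the degenerate
{0} while the error floor still produces the occasional edited-looking
read; at `e = 0.001` and pooled depth ≈ 600 the difference between `p` and
`p_obs` is ≤ 0.001 everywhere else. The double-mutant null is checked
separately and more stringently: fewer than 1% of double-mutant site
estimates may clear the 1% rate filter.

## Problem sizes and what the tests show

The validation suite runs the generator at 500–2,000 sites, coverage mean
200 and three replicates — sizes chosen so each property is measured on
thousands of site × genotype pairs while a full run of the suite stays
interactive. Under those conditions: pooled estimates fall inside their
exact 99% binomial intervals for ≥ 98% of pairs; ≥ 95% of planted classes
are recovered when control rates lie in [0.2, 0.8] (misclassification
concentrates, as expected, at multipliers adjacent to the 0.10/1.50
thresholds and at high relative noise); the double-mutant null holds with
margin; and the hyperediting sweep agrees exactly with its brute-force
oracle.

The generator emulates the design's structure, not real tissue: uniform
sequence (no real SINE consensus, so context matrices are flat off-center by
construction), independent sites (no linkage between neighboring cluster
sites' rates), no alignment artifacts, no expression-level variation beyond
NB depth, and identical WT and double-het true rates. Passing tests
therefore demonstrate the correctness of the arithmetic, filters, detector
and classifier — not that any biological claim about a real editome would
reproduce.

## Known limitations

* The differential statistic is a two-proportion z, not a
  Dirichlet-multinomial model; scores are comparable in role but not in
  value to JACUSA-style callers.
* Duplicate-read removal and alignment are input contracts, not package
  functionality: pileup counts are assumed deduplicated and correctly
  stranded.
* BAM input is out of scope; counts arrive as TSV (an adapter producing the
  pileup schema is the natural extension point).
* `UNCLASSIFIED` absorbs boundary-exact and single-sided-inhibits patterns;
  analyses caring about those cases should inspect the relative rates
  directly.
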