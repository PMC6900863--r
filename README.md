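# editomekit

Quantification and ADAR-specificity classification of A-to-I RNA editing
from multi-genotype RNA-seq pileup counts.

## The problem

Adenosine-to-inosine (A-to-I) editing, written by the deaminases ADAR1 and
ADAR2, is read as guanosine by sequencers: an edited site shows an A→G
mismatch on the transcribed strand (T→C on the reference forward strand for
minus-strand sites in a stranded library). Genetic designs that combine an
ADAR1 editing-dead allele, an ADAR2 knockout, and their compound mutant make
it possible to ask, site by site, which enzyme writes each editing event.
`editomekit` implements the count-level analysis such a design needs:

- **Editing rate per genotype.** At site *s* with per-replicate edited read
  counts *e₁…e₃* and informative depths *n₁…n₃*, the pooled rate is
  *r = Σeᵢ / Σnᵢ* (summation before division — the depth-weighted estimate).
  Sites require pooled depth ≥ 50 in **every** genotype and rate ≥ 0.01 in
  both control genotypes (WT and the double-het) to be considered.
- **Differential editing.** For genotypes *a, b* with pooled counts
  (*e_a, n_a*), (*e_b, n_b*) and *p̂ = (e_a+e_b)/(n_a+n_b)*, the statistic is
  the pooled two-proportion *z = (r_a − r_b) / √(p̂(1−p̂)(1/n_a + 1/n_b))*;
  calls use |z| ≥ 5.
- **ADAR specificity.** With control level *c* = mean(WT, dHet) and relative
  rates rel₁ (ADAR1-dead / c) and rel₂ (ADAR2-null / c): **shared** when both
  lie in (0.10, 1.50); **ADAR1-specific** when rel₁ < 0.10 with rel₂ retained
  in [0.10, 1.50] (and the "ADAR2 inhibits" variant when rel₂ > 1.50);
  symmetrically for ADAR2.
- **Hyperediting.** A site is hyperedited when ≥ 10 sites fall within a
  100-bp window; chained windows are merged into regions.
- **Annotation & context.** Gene part (promoter > 3′UTR > exon > intron >
  intergenic), B1/B2 SINE repeat family, and strand-adjusted nucleotide
  frequency matrices around the edited adenosine.

A deterministic simulator generates a toy genome, an editome with planted
specificity classes and repeat-embedded hyperedited clusters, and
genotype-structured replicate pileups (negative-binomial coverage, binomial
edited-read sampling, a small uniform error floor) with full ground truth, so
every stage of the pipeline can be validated against known answers.

## Worked example

```r
library(editomekit)
sim <- sim_config(seed = 42, n_selective_sites = 500, n_cluster_regions = 10)
res <- run_pipeline(sim, analysis_config(), outdir = "demo")
```

The run logs each stage and writes every artifact (FASTA genome, BED
clusters/regions, TSV sites/pileups/estimates/calls, a JSON manifest with
per-file checksums) to `demo/`:

```
[simulate] 600 sites (100 in clusters), 9000 pileup rows
[quantify] 3000 site x genotype estimates; 600 of 600 sites pass depth >= 50 and control rate >= 0.01
[differential] 1800 calls across 3 comparison(s), 1296 significant
[classify] 600 considered sites labeled (311 SHARED)
[hyperediting] 10 region(s), 100 of 600 sites hyperedited
```

At the default coverage (mean 200 per replicate, three replicates) every site
clears the depth and control-rate filters; 598 of 600 sites are significantly
different between the editing-free double mutant and its control (the two
misses are low-rate sites near the detection floor), and the class tally
(311 shared, 75 + 33 ADAR1-specific, 135 + 33 ADAR2-specific, 13 unclassified)
recovers the planted mixture. A classified site looks like:

```
 chrom  pos strand  rate_WT rate_ADAR1_E861A rate_ADAR2_KO control_rate rel_a1 rel_a2  label
  chr1  775      -   0.2270           0.0251        0.3060       0.2294  0.109  1.334 SHARED
```

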