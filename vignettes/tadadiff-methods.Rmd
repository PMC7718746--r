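---
title: "tadadiff: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tadadiff: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `tadadiff` computes, the assumptions behind each
stage, the parameters that matter, and what the synthetic-data tests do and
do not establish.

## The measurement model

Targeted DamID reads out protein-DNA contact as adenine methylation at GATC
sites, recovered by DpnI digestion and sequencing of the fragments between
cut points. Two facts shape the whole pipeline:

* **The GATC fragment is the resolution unit.** DpnI cuts GA^TC (blunt), so
  a motif at 0-based offset $s$ yields a cut at $s+2$, and fragments tile
  each chromosome exactly. GATC is its own reverse complement, so a
  single-strand scan is strand-complete and all fragment-transcript overlap
  is strand-agnostic.
* **Occupancy is a ratio.** The Dam-only sample controls for accessibility;
  the per-fragment signal is $\log_2(\mathrm{fusion}/\mathrm{Dam})$ after
  depth normalization. Ratios can be negative genome-wide, which is why the
  differential analysis needs a numerator filter (below).

### Ratio tracks

`compute_ratio_track` equalizes both samples to reads-per-million and adds a
pseudocount inside the log:

$$v_i = \log_2\frac{f_i s_f + c}{d_i s_d + c}, \qquad s = 10^6/\text{total}.$$

Choices made here, each declared so tests can be exact:

* Normalization is plain RPM equalization with pseudocount $c = 0.5$
  (configurable). The upstream tool the field uses for mapping performs a
  kernel-density Dam-matching step; treating normalization as a simple,
  fully specified rule keeps this artifact self-contained. The pseudocount
  is applied *after* depth scaling so the zero-count floor does not depend
  on sequencing depth.
* `scale_by_sd` divides by the *population* (1/n) standard deviation,
  unweighted by fragment length — the simplest reading of "scaled by its
  standard deviation" — and is idempotent once applied.
* Replicate averaging is the unweighted fragment-wise mean; no clipping of
  extreme values is applied anywhere.

### Occupancy calling

A transcript's occupancy is the fragment-length-weighted mean of the track
over its assigned fragments (transcript span includes introns: Pol II
occupies whole transcription units). Significance is empirical: the null
re-draws the transcript's weighted mean after a genome-wide shuffle of
(length, value) fragment pairs, keeping the pairing so long fragments carry
their own values. With add-one smoothing,

$$p = \frac{1 + \#\{\text{permutations} \ge \text{observed}\}}{1 + n_{perm}},$$

followed by Benjamini–Hochberg adjustment; a transcript is called at
FDR < 0.01, and genes inherit their most significant transcript (ties:
more fragments, then lexicographic id). The original analysis used an
external Perl script whose internal statistic this package does not restate;
equivalence is not claimed — the permutation null is distribution-free,
testable by exhaustive enumeration on toy genomes, and its type-I error is
part of the acceptance surface.

Numerical choices: `min_fragments = 2` (a one-fragment "mean" involves no
averaging; exclusions are listed, never silent); add-one smoothing keeps
$p > 0$ so BH is well defined; permutation count must give the FDR room —
with a few hundred transcripts, the smoothed p-value floor at
$n_{perm} = 1000$ BH-adjusts to ≈ 0.012, above the 0.01 bar, so the
pipeline orchestrator defaults to $n_{perm} = 4000$. Ties at the observed
statistic count as exceedances (conservative).

### Differential occupancy

Knockdown and control replicate tracks are subtracted fragment-wise,
**paired by replicate index** (the pairing key is otherwise arbitrary and is
declared rather than guessed), and the replicate difference tracks are
averaged. The same permutation machinery then runs twice — once for
enrichment, once on the negated track for depletion — with BH within each
direction, because up- and down-gene lists are reported separately. Both
directions share one permutation stream, which makes the analysis exactly
antisymmetric under swapping the genotypes (an invariant the tests check).

Two filters follow:

* **Numerator filter** (up-genes): a gene can gain signal significantly yet
  still be unbound (negative ratio) in both genotypes; reported up-genes
  must also be significantly Pol II-occupied in the knockdown genotype's own
  analysis. Exclusions record a reason.
* **Fold-change gate** (down-genes): $|\Delta| > \log_2 1.3 = 0.379$.
  The gate applies to down-genes only; reported up-gene effect sizes in this
  experimental system are small (0.047–0.61 log2), so up-calls are
  threshold-free beyond the FDR.

Significance is computed on the replicate-averaged difference track (rather
than requiring each replicate pair separately); replicate concordance enters
through the averaging. `locus_delta` is the weighted mean over the union of
a gene's transcript fragments; per-isoform values are available
(`isoform_ratios`), with the best isoform reported alongside.

### Polycomb loss filter

Dam-Pc replicate tracks are SD-scaled, then averaged, and gene-level
occupancy is the same weighted mean. A gene passes iff it (a) has
significant Dam-Pc occupancy in control, (b) significant Dam-Pol II
occupancy in both genotypes (same machinery, same α = 0.01 — the one stated
threshold is applied uniformly), and (c) its scaled Pc occupancy is > 1 in
control and < 1 in knockdown. The 1.0 threshold is interpreted on the
SD-scaled, replicate-averaged axis (scaling is described immediately before
this filter in the source protocol), and the functions refuse unscaled
input rather than silently mis-scaling. Occupancy is evaluated gene-wide
(weighted mean), not at a within-locus peak; this is noted as a choice, not
inferred.

### Phenotype statistics

Printed percentage tables are converted back to integer counts by
`round(percent · n / 100)` with a hard consistency check: the reconstructed
count must reproduce the printed percentage at its printed precision, and
the function errors rather than guesses otherwise. Every cell of the two
packaged tables passes this round-trip.

The two-tailed Fisher test uses the point-probability method — summing all
tables with the observed margins whose hypergeometric probability does not
exceed the observed one (with the conventional $10^{-7}$ relative tie
tolerance) — evaluated in log space from binomial coefficients. This
definition was adopted because it exactly reproduces the verifiable
published p-value (0.0043) from the reconstructed table; a mid-p variant
would not. Wilson intervals use score-test inversion without continuity
correction; $x = 0$ and $x = n$ clamp to 0 and 1 exactly.

## The synthetic-data world

The generator states one concrete world and keeps it fixed:

| knob | default | why |
|---|---|---|
| genotypes × replicates | 2 × 2 | two biological replicates per condition, pooled discs → one count vector each |
| genome | 4 × 500 kb | ≈ 7,800 GATC fragments: large enough for a stable permutation null, small enough for desk-scale runs |
| GATC rate | 1/256 per bp | expectation under uniform base composition |
| genes | 200, of which 20 de-repressed | matches the documented recovery design (200 genes, 20 de-repressed, effect +1 log2) |
| effect size | +1 log2 Pol II in knockdown | documented recovery design |
| de-repressed control occupancy | expressed-gene distribution N(1.5, 0.4), floored at 1 | the published candidate universe is genes significantly expressed in *both* genotypes; silent-in-control genes could never enter it |
| Pc occupancy (control / knockdown) | 2.0 / 0.25 | Pc domains are strongly bound in control; at de-repressed loci the knockdown signal collapses (these loci cross the scaled 1.0 threshold downward) |
| library size | 10^6 reads | free choice; depths were not published |
| dispersion | 0.03 | calibrated so replicate ratio-track Pearson r falls in the published 0.52–0.7 band — the one calibration the design prescribes |

Counts are drawn as a gamma-weighted multinomial at fixed library size
(a negative-binomial vector conditioned on its total): expected counts are
proportional to fragment length × $2^{\text{occupancy}}$, marginals are NB
with the configured dispersion to close approximation, and the library size
is conserved exactly — an unconditioned NB draw would violate the stated
conservation property at these defaults. Occupancy acts multiplicatively
($2^{\log_2\text{signal}}$) so the generative scale matches the analysis
scale; the Dam-only control models uniform accessibility.

### What the synthetic tests do not establish

* No read-level simulation: no mapping ambiguity, sequence-composition or
  GC bias, so the tests cannot detect normalization failures those would
  cause.
* The Dam control is uniform; real accessibility structure would correlate
  Dam and fusion counts and change the ratio noise model.
* Because the fusion sample's total is fixed, strong occupancy at some loci
  depresses measured occupancy elsewhere (compositional shift ≈ −0.5 log2
  at the defaults). This is realistic for sequencing data and the
  permutation test is insensitive to it, but absolute occupancy values are
  not comparable across configurations.
* All Pc-domain genes are de-repressed ones; stable Polycomb domains that
  keep their Pc binding in the knockdown are not simulated, so the Pc
  filter's specificity against *retained* domains is exercised only by the
  threshold unit tests, not the recovery simulation.
* A green recovery test shows the pipeline finds a +1 log2 effect at the
  calibrated noise level in this world; it says nothing about the published
  17- and 110-gene lists, which derive from deposited sequencing data that
  this package deliberately does not require.

### Known limitation: the Pc-filter conjunction is power-marginal

At the noise level pinned by the 0.52–0.7 concordance band, control-genotype
Pol II detection of genes with occupancy near 1 log2 is ~90–95% per gene at
FDR < 0.01. The Pc filter conjoins three significance calls over 20 genes,
so its truth overlap fluctuates around the 90% acceptance bar across seeds
(≈ 0.70–0.95, typically ≥ 0.85). All the levers that would raise power are
fixed by the stated design (α, replicate count, the permutation null), so
this marginality is documented rather than tuned away.

## Reproducibility and error policy

Every stochastic stage is seeded, and per-sample streams are derived
deterministically from `(seed, genotype, sample kind, replicate)`.
Structural mistakes — mismatched fragment maps, unequal replicate counts,
scaled tracks where unscaled are required (and vice versa), unknown
chromosomes or gene ids, a numerator table from the wrong genotype,
percentage cells no integer count can explain — are hard errors naming the
offender, never warnings or silent coercions.
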