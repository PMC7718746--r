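# tadadiff

Targeted DamID (TaDa) profiles where a protein of interest sits on the
genome by fusing it to the *E. coli* Dam methyltransferase: GATC sites the
fusion contacts become adenine-methylated, are cut by DpnI, and are read out
by sequencing. The unit of signal is the **GATC fragment** — the interval
between consecutive DpnI cut points — and occupancy is the per-fragment
log2 ratio of the fusion sample over a Dam-only accessibility control.

`tadadiff` implements, as a tested and reusable R pipeline, the analysis
used to ask which genes change RNA Pol II occupancy when a Polycomb-group
repressor is knocked down in *Drosophila* wing discs, and whether those
genes sit in Polycomb (Pc) binding domains:

1. **Digestion** — build the GATC fragment map of a genome and assign
   fragments to transcripts (`build_fragment_map`,
   `map_fragments_to_transcripts`).
2. **Ratio tracks** — per-replicate log2(Dam-fusion/Dam) tracks with
   reads-per-million equalization and a pseudocount; SD-scaling and
   replicate averaging (`compute_ratio_track`, `scale_by_sd`,
   `average_tracks`, `replicate_correlation`).
3. **Occupancy calling** — per-transcript length-weighted mean occupancy
   with an empirical one-sided permutation p-value (genome-wide shuffle of
   (length, value) fragment pairs), Benjamini–Hochberg FDR at a 1%
   threshold, and reduction to genes via the most significant transcript
   (`occupancy_significance`, `gene_table_from_transcripts`).
4. **Differential occupancy** — replicate-paired subtraction of genotype
   tracks, two one-sided permutation tests on the averaged difference
   track, a numerator filter (up-genes must be Pol II-bound in the
   knockdown itself, because log2 ratios can be "significantly enriched"
   while negative in both genotypes), and a fold-change gate (>1.3) for
   down-genes (`difference_tracks`, `differential_genes`).
5. **Polycomb loss filter** — genes with significant Dam-Pc occupancy in
   control, Pol II occupancy in both genotypes, and scaled Pc occupancy
   crossing 1.0 downward in the knockdown (`pc_loss_filter`).
6. **Phenotype statistics** — reconstruction of integer counts from printed
   percentage tables, two-tailed Fisher exact tests (point-probability
   method) against a control genotype, and Wilson score intervals without
   continuity correction (`compare_genotypes`, `fisher_exact_two_tailed`,
   `wilson_ci`).
7. **Synthetic data** — a generator for toy genomes, gene models and
   negative-binomial DamID counts with known ground truth
   (`sim_config`, `simulate_experiment`), so every stage is testable
   without external downloads.

For a 2×2 table with margins fixed, the two-tailed Fisher p-value is

p = Σ { P(T) : P(T) ≤ P(T_obs) },  P(T) hypergeometric,

and the Wilson interval for x successes in n trials is

( p̂ + z²/2n ± z·√( p̂(1−p̂)/n + z²/4n² ) ) / (1 + z²/n),  p̂ = x/n.

## Worked example: synthetic knockdown experiment

```r
library(tadadiff)
cfg <- sim_config(seed = 1, n_chromosomes = 2, chromosome_length = 150000,
                  n_genes = 30, n_derepressed = 5, library_size = 5e5,
                  gene_fragments = c(6, 12))
res <- run_damid_pipeline(cfg, n_perm = 2000)
round(unlist(res$replicate_r), 2)
#>   control.Dam-PolII      control.Dam-Pc knockdown.Dam-PolII    knockdown.Dam-Pc
#>                0.63                0.47                0.73               -0.02
dt <- res$differential
dt[dt$reported, c("gene_id", "locus_delta", "direction", "fdr", "bound_in_numerator")]
#>   gene_id locus_delta direction     fdr bound_in_numerator
#> 1    g016       0.807        up 0.00516               TRUE
#> 2    g019       0.728        up 0.00516               TRUE
#> 3    g027       0.978        up 0.00516               TRUE
#> 4    g029       0.985        up 0.00516               TRUE
```

Four of the five genes simulated with a +1 log2 Pol II gain are reported as
de-repressed (`locus_delta` is the length-weighted mean of the averaged
knockdown−control difference track over each gene locus); no unchanged gene
is. The Polycomb filter finds the same loci with control Pc occupancy ~3.4
SD units and knockdown occupancy well below 1:

```r
head(res$pc_filter[res$pc_filter$passes, 1:3], 2)
#>   gene_id pc_occ_control pc_occ_knockdown
#> 3    g016           3.49            0.328
#> 4    g027           3.35            0.757
```

## Worked example: phenotype tables

The package ships transcriptions of the published categorical
eversion-outcome tables. Counts are reconstructed from printed percentages
(with a consistency check), dichotomized on the "normal" category, and
tested against the designated control:

```r
res <- compare_genotypes(load_rescue_table(), control_label = "Sce.IR_alone")
res[res$genotype %in% c("Sce.IR_alone", "Sce.IR_AbdB.IR-BL35647", "Sce.IR_GFP"), ]
#>                  genotype   x   n proportion  lower  upper p_two_tailed
#> 1            Sce.IR_alone  15 379     0.0396 0.0241 0.0643           NA
#> 3  Sce.IR_AbdB.IR-BL35647 187 397     0.4710 0.4224 0.5202     3.93e-48
#> 10             Sce.IR_GFP   8 165     0.0485 0.0248 0.0927     6.46e-01
```

Knocking down Abd-B alongside the repressor rescues normal eversion from 4%
to 47% (p ≈ 4e-48), while a GFP co-expression control does not (p = 0.6464,
matching the published value). `lower`/`upper` are 95% Wilson bounds.

## Command line

Every stage has a CLI subcommand (`simulate`, `digest`, `ratio`,
`aggregate`, `occupancy`, `diff`, `pcfilter`, `phenostats`):

```sh
Rscript -e 'tadadiff::damid_cli()' simulate --seed 7 --config config.json --outdir sim/
Rscript -e 'tadadiff::damid_cli()' digest --fasta sim/genome.fasta --out-bed fragments.bed
```

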