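# Shared fixture builders. All synthetic; nothing is read from disk except
# the packaged phenotype/gene tables.

config_with <- function(defaults, overrides) {
  do.call(sim_config, utils::modifyList(defaults, overrides))
}

# Small two-chromosome world: fast enough for per-module tests.
tiny_config <- function(seed = 7L, ...) {
  config_with(list(seed = seed, n_chromosomes = 2L,
                   chromosome_length = 60000L, n_genes = 12L,
                   n_derepressed = 3L, library_size = 2e5,
                   gene_fragments = c(6L, 12L)), list(...))
}

# Signal-free world for calibration runs: every gene silent.
null_config <- function(seed = 1L, ...) {
  config_with(list(seed = seed, n_chromosomes = 1L,
                   chromosome_length = 150000L, n_genes = 35L,
                   n_derepressed = 0L, frac_expressed = 0,
                   library_size = 5e5, gene_fragments = c(6L, 12L)),
              list(...))
}

# Map with chosen fragment lengths, built through the public digestion path:
# a sequence is crafted whose GATC cut points produce the requested lengths.
map_with_lengths <- function(lengths, chrom = "chrA") {
  stopifnot(all(lengths >= 4))
  bounds <- cumsum(lengths)
  cuts <- bounds[-length(bounds)]
  total <- bounds[length(bounds)]
  letters <- rep("A", total)
  for (cut in cuts) letters[(cut - 1):(cut + 2)] <- c("G", "A", "T", "C")
  seqs <- stats::setNames(paste(letters, collapse = ""), chrom)
  map <- build_fragment_map(seqs)
  stopifnot(identical(map$end - map$start, as.integer(lengths)))
  map
}

# Bare track on an arbitrary map with full control over values and flags.
toy_track <- function(map, values, ...) {
  tadadiff:::new_ratio_track(map, values, ...)
}

# Assignment for transcripts given as list(gene_id = list(tx_id = c(start, end))).
toy_assignment <- function(map, tx_df) {
  map_fragments_to_transcripts(map, tx_df)
}

# Average of simulated Pol II ratio tracks for one genotype.
avg_polII_track <- function(sim, genotype, pseudocount = 0.5) {
  average_tracks(lapply(seq_along(sim$counts[[genotype]][["Dam-PolII"]]),
                        function(r) {
    compute_ratio_track(sim$counts[[genotype]][["Dam-PolII"]][[r]],
                        sim$counts[[genotype]][["Dam"]][[r]], sim$map,
                        pseudocount = pseudocount, sample_kind = "Dam-PolII",
                        genotype = genotype, replicate = r)
  }))
}
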