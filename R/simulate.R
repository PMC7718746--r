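#' Simulation configuration
#'
#' Collects every knob of the synthetic DamID world and validates it. The
#' defaults describe the experiment the pipeline is designed for: two
#' genotypes (control, knockdown), 2 biological replicates each (pooled
#' discs, one count vector per replicate), a 2 Mb toy genome with GATC
#' density 1/256 (the expectation for uniform base composition), 200 genes
#' of which 20 sit in Polycomb domains and are de-repressed by +1 log2 unit
#' of Pol II occupancy in the knockdown while their Pc signal collapses.
#' The negative-binomial dispersion default (0.03) is calibrated so that
#' replicate ratio-track Pearson correlations fall in the experimentally
#' reported 0.52-0.7 band.
#'
#' @param seed Integer master seed; every stage derives its stream from it.
#' @param n_chromosomes,chromosome_length Genome shape (bp;
#'   \code{chromosome_length >= 1000}).
#' @param gatc_rate Expected GATC motifs per bp, in \[0, 0.25). 0 is allowed
#'   as a degenerate override (no cut sites).
#' @param n_genes Number of non-overlapping genes to place.
#' @param isoforms_per_gene Integer range \code{c(min, max)} of isoforms.
#' @param n_derepressed Number of Polycomb-domain genes gaining Pol II in the
#'   knockdown (\code{<= n_genes}).
#' @param effect_size Additive log2 Pol II gain in the knockdown.
#' @param replicates Biological replicates per condition (>= 2).
#' @param library_size Total reads per sample.
#' @param dispersion Negative-binomial overdispersion (variance
#'   \code{mu + dispersion * mu^2}); 0 gives Poisson-like (multinomial)
#'   counts.
#' @param frac_expressed Fraction of non-derepressed genes transcribed in
#'   both genotypes.
#' @param expressed_mean,expressed_sd Log2 Pol II occupancy distribution of
#'   expressed genes.
#' @param derepressed_min_base Floor on the control-genotype log2 Pol II
#'   occupancy of de-repressed genes. The differential and Polycomb filters
#'   admit only genes detectably transcribed in both genotypes, so
#'   de-repressed genes draw from the expressed-gene occupancy distribution
#'   truncated at this floor (default 1 log2 unit).
#' @param pc_occupancy_control,pc_occupancy_knockdown Mean Pc signal (log2
#'   scale) of Polycomb-domain genes in each genotype; control > knockdown
#'   >= 0.
#' @param gene_fragments,gap_fragments Integer ranges (in GATC fragments) of
#'   gene body sizes and intergenic gaps used when placing genes.
#' @return A validated \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chromosome_length = 5e5,
                       gatc_rate = 1 / 256,
                       n_genes = 200L,
                       isoforms_per_gene = c(1L, 3L),
                       n_derepressed = 20L,
                       effect_size = 1,
                       replicates = 2L,
                       library_size = 1e6,
                       dispersion = 0.03,
                       frac_expressed = 0.4,
                       expressed_mean = 1.5,
                       expressed_sd = 0.4,
                       derepressed_min_base = 1,
                       pc_occupancy_control = 2,
                       pc_occupancy_knockdown = 0.25,
                       gene_fragments = c(10L, 24L),
                       gap_fragments = c(2L, 8L)) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              gatc_rate = gatc_rate, n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              n_derepressed = as.integer(n_derepressed),
              effect_size = effect_size, replicates = as.integer(replicates),
              library_size = library_size, dispersion = dispersion,
              frac_expressed = frac_expressed, expressed_mean = expressed_mean,
              expressed_sd = expressed_sd,
              derepressed_min_base = derepressed_min_base,
              pc_occupancy_control = pc_occupancy_control,
              pc_occupancy_knockdown = pc_occupancy_knockdown,
              gene_fragments = as.integer(gene_fragments),
              gap_fragments = as.integer(gap_fragments))
  stopifnot(cfg$replicates >= 2L,
            cfg$n_derepressed <= cfg$n_genes,
            cfg$gatc_rate >= 0, cfg$gatc_rate < 0.25,
            cfg$n_chromosomes >= 1L,
            cfg$library_size > 0, cfg$dispersion >= 0,
            length(cfg$isoforms_per_gene) == 2L,
            cfg$isoforms_per_gene[1] >= 1L,
            cfg$pc_occupancy_control >= 0, cfg$pc_occupancy_knockdown >= 0,
            cfg$pc_occupancy_control > cfg$pc_occupancy_knockdown ||
              cfg$n_derepressed == 0L)
  if (cfg$chromosome_length < 1000L) {
    stop("chromosome_length < 1000: too few fragments to analyze")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-sample seed derived from the master seed; kept < 2^31.
sample_seed <- function(cfg, offset) {
  (abs(cfg$seed) %% 1000000L) * 2000L + as.integer(offset)
}

# Remove every GATC occurrence from a letter vector by mutating the motif's
# final C to A; a single left-to-right pass cannot create new motifs, but we
# re-scan until clean for safety.
strip_gatc <- function(letters) {
  repeat {
    s <- paste(letters, collapse = "")
    sites <- find_gatc_sites(s)
    if (length(sites) == 0L) return(letters)
    letters[sites + 4L] <- "A"
  }
}

#' Generate a random genome with known GATC motif positions
#'
#' Each chromosome is built as a GATC-free random background into which
#' motifs are planted at Binomial(\code{length}, \code{gatc_rate}) density at
#' non-overlapping uniform positions. Because GATC cannot overlap itself and
#' the background is motif-free, the planted positions are exactly the motif
#' positions of the emitted sequence. Deterministic given the seed.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{sequences} (named character vector) and
#'   \code{gatc_sites} (per-chromosome 0-based truth offsets).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sample_seed(config, 1L))
  L <- config$chromosome_length
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  sequences <- character(0)
  sites_out <- list()
  for (chr in chroms) {
    letters <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    letters <- strip_gatc(letters)
    n_mot <- stats::rbinom(1L, L, config$gatc_rate)
    starts <- integer(0)
    if (n_mot > 0L) {
      cand <- sort(sample.int(L - 3L, n_mot))
      keep <- logical(length(cand))
      last <- -4L
      for (i in seq_along(cand)) {       # enforce non-overlap (spacing >= 4)
        if (cand[i] - last >= 4L) { keep[i] <- TRUE; last <- cand[i] }
      }
      starts <- cand[keep]
      for (s in starts) letters[s:(s + 3L)] <- c("G", "A", "T", "C")
    }
    sequences[[chr]] <- paste(letters, collapse = "")
    sites_out[[chr]] <- as.integer(starts - 1L)  # 0-based
  }
  list(sequences = sequences, gatc_sites = sites_out)
}

#' Generate a gene/transcript annotation and its simulation truth
#'
#' Genes are placed sequentially along each chromosome as runs of whole GATC
#' fragments (10-24 fragments by default, so every gene spans well over 5
#' fragments) separated by short gaps; isoforms are nested sub-spans sharing
#' the gene body. \code{n_derepressed} genes are flagged as Polycomb-domain
#' genes: they carry \code{delta_polII_knockdown = effect_size}, a positive
#' control Pc signal and a reduced knockdown Pc signal. A further
#' \code{frac_expressed} of the remaining genes are constitutively
#' transcribed; the rest are silent.
#'
#' @param genome Output of \code{\link{simulate_genome}}.
#' @param config The same \code{\link{sim_config}}.
#' @return List with \code{genes}, \code{transcripts} (0-based half-open
#'   coordinates), \code{truth} (one row per gene: \code{gene_id},
#'   \code{base_polII_occupancy}, \code{delta_polII_knockdown},
#'   \code{pc_domain}, \code{pc_occupancy_control},
#'   \code{pc_occupancy_knockdown}), and the \code{map} used for placement.
#' @export
simulate_annotation <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sample_seed(config, 2L))
  map <- build_fragment_map(genome$sequences)
  if (config$n_genes == 0L) {
    empty_tx <- data.frame(transcript_id = character(0), gene_id = character(0),
                           chrom = character(0), start = integer(0),
                           end = integer(0), stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = character(0), base_polII_occupancy = numeric(0),
                        delta_polII_knockdown = numeric(0), pc_domain = logical(0),
                        pc_occupancy_control = numeric(0),
                        pc_occupancy_knockdown = numeric(0),
                        stringsAsFactors = FALSE)
    return(list(genes = empty_tx[, c("gene_id", "chrom", "start", "end")][0, ],
                transcripts = empty_tx, truth = truth, map = map))
  }
  genes <- list(); txs <- list(); g <- 0L
  for (chr in unique(map$chrom)) {
    rows <- which(map$chrom == chr)
    i <- 2L  # skip the first fragment of each chromosome
    while (g < config$n_genes) {
      nf <- sample(seq(config$gene_fragments[1], config$gene_fragments[2]), 1L)
      if (i + nf - 1L > length(rows) - 1L) break
      g <- g + 1L
      gid <- sprintf("g%03d", g)
      g_start <- map$start[rows[i]]
      g_end <- map$end[rows[i + nf - 1L]]
      genes[[g]] <- data.frame(gene_id = gid, chrom = chr, start = g_start,
                               end = g_end, stringsAsFactors = FALSE)
      k <- sample(seq(config$isoforms_per_gene[1], config$isoforms_per_gene[2]), 1L)
      tx <- vector("list", k)
      for (j in seq_len(k)) {
        if (j == 1L) { a <- i; b <- i + nf - 1L } else {
          max_trim <- max(0L, (nf - 6L) %/% 2L)
          a <- i + sample(0:max_trim, 1L)
          b <- i + nf - 1L - sample(0:max_trim, 1L)
        }
        tx[[j]] <- data.frame(
          transcript_id = sprintf("%s-R%s", gid, LETTERS[j]), gene_id = gid,
          chrom = chr, start = map$start[rows[a]], end = map$end[rows[b]],
          stringsAsFactors = FALSE)
      }
      txs[[g]] <- do.call(rbind, tx)
      i <- i + nf + sample(seq(config$gap_fragments[1], config$gap_fragments[2]), 1L)
    }
    if (g >= config$n_genes) break
  }
  if (g < config$n_genes) {
    stop(sprintf("genome too small to place %d non-overlapping genes (placed %d)",
                 config$n_genes, g))
  }
  genes <- do.call(rbind, genes)
  transcripts <- do.call(rbind, txs)
  rownames(genes) <- rownames(transcripts) <- NULL

  derepressed <- sample(genes$gene_id, config$n_derepressed)
  rest <- setdiff(genes$gene_id, derepressed)
  expressed <- rest[stats::runif(length(rest)) < config$frac_expressed]
  base <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  base[expressed] <- pmax(
    0.5, stats::rnorm(length(expressed), config$expressed_mean, config$expressed_sd))
  base[derepressed] <- pmax(
    config$derepressed_min_base,
    stats::rnorm(length(derepressed), config$expressed_mean, config$expressed_sd))
  truth <- data.frame(
    gene_id = genes$gene_id,
    base_polII_occupancy = unname(base[genes$gene_id]),
    delta_polII_knockdown = ifelse(genes$gene_id %in% derepressed,
                                   config$effect_size, 0),
    pc_domain = genes$gene_id %in% derepressed,
    pc_occupancy_control = ifelse(genes$gene_id %in% derepressed,
                                  config$pc_occupancy_control, 0),
    pc_occupancy_knockdown = ifelse(genes$gene_id %in% derepressed,
                                    config$pc_occupancy_knockdown, 0),
    stringsAsFactors = FALSE)
  list(genes = genes, transcripts = transcripts, truth = truth, map = map)
}

# Per-fragment log2 signal for one (genotype, sample_kind) combination.
fragment_signal <- function(annotation, fragment_map, truth, genotype,
                            sample_kind) {
  sig <- numeric(nrow(fragment_map))
  if (sample_kind == "Dam" || nrow(truth) == 0L) return(sig)
  gene_level <- switch(sample_kind,
    "Dam-PolII" = truth$base_polII_occupancy +
      if (genotype == "knockdown") truth$delta_polII_knockdown else 0,
    "Dam-Pc" = if (genotype == "knockdown") truth$pc_occupancy_knockdown
               else truth$pc_occupancy_control,
    stop("unknown sample_kind: ", sample_kind))
  genes <- annotation$genes
  frag_gr <- map_granges(fragment_map)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, frag_gr)
  gl <- gene_level[match(genes$gene_id, truth$gene_id)]
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  # genes are non-overlapping by construction; max() guards toy overlaps
  agg <- tapply(gl[qh], sh, max)
  sig[as.integer(names(agg))] <- pmax(sig[as.integer(names(agg))], agg)
  sig
}

#' Simulate per-fragment DamID counts for one sample
#'
#' Expected counts are proportional to fragment length times
#' \code{2^signal}, where the signal is the genotype-adjusted log2 occupancy
#' of the overlapping gene (0 for the Dam-only accessibility control and for
#' intergenic fragments). Counts are drawn as a gamma-weighted multinomial at
#' the configured library size, i.e. a negative-binomial vector with the
#' configured per-fragment dispersion conditioned on its total, so the
#' library size is conserved exactly. Deterministic given
#' \code{(seed, genotype, sample_kind, replicate)}.
#'
#' @param annotation Output of \code{\link{simulate_annotation}}.
#' @param fragment_map The \code{gatc_map} the counts are aligned to.
#' @param truth The simulation truth table.
#' @param genotype \code{"control"} or \code{"knockdown"}.
#' @param sample_kind \code{"Dam"}, \code{"Dam-PolII"} or \code{"Dam-Pc"}.
#' @param replicate Replicate index (1-based).
#' @param config The \code{\link{sim_config}}.
#' @return Integer vector of counts, one per fragment, summing to
#'   \code{library_size}.
#' @export
simulate_damid_counts <- function(annotation, fragment_map, truth, genotype,
                                  sample_kind, replicate, config) {
  genotype <- match.arg(genotype, c("control", "knockdown"))
  sample_kind <- match.arg(sample_kind, c("Dam", "Dam-PolII", "Dam-Pc"))
  stopifnot(inherits(config, "sim_config"), replicate >= 1L)
  geno_i <- match(genotype, c("control", "knockdown"))
  kind_i <- match(sample_kind, c("Dam", "Dam-PolII", "Dam-Pc"))
  set.seed(sample_seed(config, 100L + geno_i * 400L + kind_i * 100L +
                         as.integer(replicate)))
  sig <- fragment_signal(annotation, fragment_map, truth, genotype, sample_kind)
  len <- fragment_map$end - fragment_map$start
  w <- len * 2^sig
  if (config$dispersion > 0) {
    shape <- 1 / config$dispersion
    w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
  }
  counts <- stats::rmultinom(1L, size = config$library_size, prob = w / sum(w))
  as.integer(counts[, 1L])
}

#' Simulate a complete DamID experiment
#'
#' Convenience wrapper running genome, annotation and count simulation for
#' every (genotype, sample kind, replicate) combination.
#'
#' @param config A \code{\link{sim_config}}.
#' @param sample_kinds Which fusion kinds to simulate alongside the Dam-only
#'   control.
#' @return List: \code{config}, \code{genome}, \code{annotation} (with
#'   \code{truth}), \code{map}, and \code{counts[[genotype]][[kind]][[rep]]}.
#' @export
simulate_experiment <- function(config = sim_config(),
                                sample_kinds = c("Dam", "Dam-PolII", "Dam-Pc")) {
  stopifnot(inherits(config, "sim_config"))
  genome <- simulate_genome(config)
  annotation <- simulate_annotation(genome, config)
  counts <- list()
  for (geno in c("control", "knockdown")) {
    counts[[geno]] <- list()
    for (kind in sample_kinds) {
      counts[[geno]][[kind]] <- lapply(seq_len(config$replicates), function(r) {
        simulate_damid_counts(annotation, annotation$map, annotation$truth,
                              geno, kind, r, config)
      })
    }
  }
  list(config = config, genome = genome, annotation = annotation,
       map = annotation$map, truth = annotation$truth, counts = counts)
}
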