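#' Write a genome to FASTA
#' @param sequences Named character vector of chromosome sequences.
#' @param path Output file.
#' @export
write_genome_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write an annotation (genes + transcripts) as GFF3
#'
#' Internal 0-based half-open coordinates are converted to GFF3's 1-based
#' inclusive convention at this boundary.
#'
#' @param annotation List with \code{genes} and \code{transcripts}
#'   data.frames (as from \code{\link{simulate_annotation}}).
#' @param path Output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes; tx <- annotation$transcripts
  gr_g <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    type = "gene", ID = g$gene_id)
  gr_t <- GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    type = "mRNA", ID = tx$transcript_id, Parent = tx$gene_id)
  rtracklayer::export(c(gr_g, gr_t), path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into 0-based gene/transcript tables
#'
#' @param path GFF3 file with \code{gene} and \code{mRNA} (or
#'   \code{transcript}) features linked by \code{Parent}.
#' @return List with \code{genes} and \code{transcripts} data.frames
#'   (0-based half-open).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_g <- type == "gene"
  is_t <- type %in% c("mRNA", "transcript")
  genes <- data.frame(
    gene_id = as.character(gr$ID[is_g]),
    chrom = as.character(GenomeInfoDb::seqnames(gr)[is_g]),
    start = GenomicRanges::start(gr)[is_g] - 1L,
    end = GenomicRanges::end(gr)[is_g],
    stringsAsFactors = FALSE)
  parent <- vapply(gr$Parent[is_t], function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  transcripts <- data.frame(
    transcript_id = as.character(gr$ID[is_t]),
    gene_id = parent,
    chrom = as.character(GenomeInfoDb::seqnames(gr)[is_t]),
    start = GenomicRanges::start(gr)[is_t] - 1L,
    end = GenomicRanges::end(gr)[is_t],
    stringsAsFactors = FALSE)
  list(genes = genes, transcripts = transcripts)
}

#' Write a GATC fragment map as BED3
#' @param map A \code{gatc_map}.
#' @param path Output file.
#' @export
write_fragment_map_bed <- function(map, path) {
  stopifnot(inherits(map, "gatc_map"))
  gr <- map_granges(map)
  GenomeInfoDb::seqlengths(gr) <-
    attr(map, "chrom_lengths")[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Rebuild a gatc_map from tiling chrom/start/end intervals; verifies the
# tiling invariant (contiguous, covering 0..len per chromosome).
map_from_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
  map <- data.frame(chrom = as.character(df$chrom),
                    start = as.integer(df$start), end = as.integer(df$end),
                    stringsAsFactors = FALSE)
  rownames(map) <- NULL
  cuts <- list(); lens <- integer(0)
  for (chr in unique(map$chrom)) {
    m <- map[map$chrom == chr, , drop = FALSE]
    if (m$start[1] != 0L || any(m$start[-1] != m$end[-nrow(m)]) ||
        any(m$end <= m$start)) {
      stop("intervals on ", chr, " do not tile the chromosome")
    }
    cuts[[chr]] <- as.integer(m$start[-1] - 2L)  # cut = motif offset + 2
    lens[[chr]] <- m$end[nrow(m)]
  }
  attr(map, "cut_sites") <- cuts
  attr(map, "chrom_lengths") <- lens
  class(map) <- c("gatc_map", "data.frame")
  map
}

#' Read a fragment map from BED3
#' @param path BED file written by \code{\link{write_fragment_map_bed}}.
#' @return A \code{gatc_map} (motif positions are inferred from the internal
#'   fragment boundaries).
#' @export
read_fragment_map_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  map_from_intervals(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr), stringsAsFactors = FALSE))
}

#' Write per-fragment counts as TSV (chrom, start, end, count)
#' @param counts Integer vector aligned to \code{map}.
#' @param map A \code{gatc_map}.
#' @param path Output file.
#' @export
write_counts_tsv <- function(counts, map, path) {
  stopifnot(inherits(map, "gatc_map"), length(counts) == nrow(map))
  utils::write.table(
    data.frame(chrom = map$chrom, start = map$start, end = map$end,
               count = as.integer(counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-fragment counts from TSV
#' @param path TSV with chrom, start, end, count.
#' @param map Optional \code{gatc_map} to validate against.
#' @return List with \code{map} (reconstructed or validated) and
#'   \code{counts}.
#' @export
read_counts_tsv <- function(path, map = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  m <- map_from_intervals(df)
  if (!is.null(map)) stop_if_map_mismatch(map, m, "counts file and map")
  list(map = if (is.null(map)) m else map, counts = as.integer(df$count))
}

#' Write a ratio track as bedGraph
#' @param track A \code{ratio_track}.
#' @param path Output file.
#' @param digits Significant digits to keep (default 9; round-trips exceed
#'   the 6-significant-digit contract).
#' @export
write_ratio_bedgraph <- function(track, path, digits = 9L) {
  stopifnot(inherits(track, "ratio_track"))
  lines <- sprintf("%s\t%d\t%d\t%s", track$map$chrom, track$map$start,
                   track$map$end, formatC(signif(track$value, digits),
                                          digits = digits, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ratio track from bedGraph
#' @param path bedGraph file.
#' @param map Optional \code{gatc_map} to validate against.
#' @param sample_kind,genotype,replicate,scaled,averaged Metadata to attach
#'   (bedGraph carries none).
#' @return A \code{ratio_track}.
#' @export
read_ratio_bedgraph <- function(path, map = NULL, sample_kind = NA_character_,
                                genotype = NA_character_, replicate = NA,
                                scaled = FALSE, averaged = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   value = gr$score, stringsAsFactors = FALSE)
  m <- map_from_intervals(df)
  value <- df$value[order(match(df$chrom, unique(df$chrom)), df$start)]
  if (!is.null(map)) { stop_if_map_mismatch(map, m, "bedGraph and map"); m <- map }
  new_ratio_track(m, value, sample_kind = sample_kind, genotype = genotype,
                  replicate = replicate, scaled = scaled, averaged = averaged)
}

#' Write the simulation truth table as TSV
#' @param truth Truth data.frame.
#' @param path Output file.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table (occupancy, differential, Pc filter) as TSV
#'
#' Stores the table's genotype/alpha attributes as \code{#key=value} header
#' comments so gene tables can be re-read with their genotype label intact.
#'
#' @param table data.frame (possibly classed).
#' @param path Output file.
#' @export
write_result_tsv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("genotype", "sample_kind", "alpha")) {
    v <- attr(table, key)
    if (!is.null(v) && !is.na(v)) writeLines(sprintf("#%s=%s", key, v), con)
  }
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene occupancy table written by \code{\link{write_result_tsv}}
#' @param path TSV file.
#' @return A \code{gene_occupancy_table} with genotype/alpha attributes.
#' @export
read_gene_table_tsv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  for (line in meta) {
    kv <- strsplit(sub("^#", "", line), "=", fixed = TRUE)[[1]]
    attr(df, kv[1]) <- if (kv[1] == "alpha") as.numeric(kv[2]) else kv[2]
  }
  class(df) <- c("gene_occupancy_table", "data.frame")
  df
}
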