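#' Find GATC motif positions in a nucleotide sequence
#'
#' Scans a sequence for every occurrence of the DpnI recognition motif
#' \code{GATC}. The motif is its own reverse complement, so a single-strand
#' scan is strand-complete, and self-overlap is impossible.
#'
#' @param sequence A single character string over \code{A,C,G,T,N}
#'   (case-insensitive), or a \code{Biostrings::DNAString}.
#' @return Integer vector of 0-based motif start offsets (possibly empty).
#' @examples
#' find_gatc_sites("AAGATCAA")  # 2
#' @export
find_gatc_sites <- function(sequence) {
  if (methods::is(sequence, "DNAString")) sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return(integer(0))
  m <- gregexpr("GATC", toupper(sequence), fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Build the GATC fragment map of a genome
#'
#' In-silico DpnI digestion: the enzyme cuts GA^TC (blunt), so each motif at
#' 0-based offset \code{s} contributes a cut point at \code{s + 2}. Fragments
#' are the half-open intervals between consecutive cut points and tile each
#' chromosome exactly from 0 to its length; a motif-free chromosome yields a
#' single whole-chromosome fragment.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   \code{Biostrings::DNAStringSet}.
#' @return A \code{gatc_map}: a data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), ordered by chromosome and
#'   position, with attributes \code{cut_sites} (per-chromosome 0-based motif
#'   offsets) and \code{chrom_lengths}.
#' @export
build_fragment_map <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), length(genome) >= 1L,
            !is.null(names(genome)), !anyDuplicated(names(genome)))
  frags <- lapply(names(genome), function(chr) {
    len <- nchar(genome[[chr]])
    sites <- find_gatc_sites(genome[[chr]])
    cuts <- sites + 2L
    bounds <- c(0L, cuts, len)
    data.frame(chrom = chr,
               start = bounds[-length(bounds)],
               end   = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, frags)
  rownames(map) <- NULL
  attr(map, "cut_sites") <- lapply(stats::setNames(names(genome), names(genome)),
                                   function(chr) find_gatc_sites(genome[[chr]]))
  attr(map, "chrom_lengths") <- vapply(genome, nchar, integer(1))
  class(map) <- c("gatc_map", "data.frame")
  map
}

#' @export
print.gatc_map <- function(x, ...) {
  cat(sprintf("GATC fragment map: %d fragments on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

# Two maps describe the same coordinate system iff chrom/start/end agree.
same_map <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(as.character(a$chrom), as.character(b$chrom)) &&
    identical(as.integer(a$start), as.integer(b$start)) &&
    identical(as.integer(a$end), as.integer(b$end))
}

stop_if_map_mismatch <- function(a, b, what = "inputs") {
  if (!same_map(a, b)) stop(what, " are not on the same GATC fragment map")
  invisible(TRUE)
}

map_granges <- function(map) {
  GenomicRanges::GRanges(
    seqnames = map$chrom,
    ranges = IRanges::IRanges(start = map$start + 1L, end = map$end))
}

#' Assign GATC fragments to transcripts
#'
#' A fragment is assigned to every transcript whose span it intersects
#' (strand-agnostic: Dam adenine methylation at GATC is palindromic). The
#' transcript span is the full genomic interval, introns included, since
#' Pol II occupies the whole transcription unit. Transcripts overlapping no
#' fragment are recorded in the \code{excluded} attribute, never dropped
#' silently.
#'
#' @param fragment_map A \code{gatc_map}.
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id}, \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), e.g. the \code{transcripts} element of
#'   \code{\link{simulate_annotation}} or \code{\link{read_annotation_gff3}}.
#' @return A \code{fragment_assignment}: list with \code{transcripts} (id
#'   table), \code{fragment_idx} (per transcript, ordered row indices into
#'   the map), \code{excluded} (transcript ids with zero fragments), and the
#'   \code{map} itself.
#' @export
map_fragments_to_transcripts <- function(fragment_map, transcripts) {
  stopifnot(inherits(fragment_map, "gatc_map"),
            all(c("transcript_id", "gene_id", "chrom", "start", "end") %in%
                  names(transcripts)))
  bad <- !(transcripts$chrom %in% unique(fragment_map$chrom))
  if (any(bad)) {
    stop("transcript(s) on unknown chromosome: ",
         paste(transcripts$transcript_id[bad], collapse = ", "))
  }
  lens <- attr(fragment_map, "chrom_lengths")
  out_of_bounds <- transcripts$start < 0 |
    transcripts$end > lens[transcripts$chrom]
  if (any(out_of_bounds)) {
    stop("transcript(s) outside chromosome bounds: ",
         paste(transcripts$transcript_id[out_of_bounds], collapse = ", "))
  }
  frag_gr <- map_granges(fragment_map)
  tx_gr <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start + 1L,
                              end = transcripts$end))
  GenomeInfoDb::seqlevels(tx_gr) <- GenomeInfoDb::seqlevels(frag_gr)
  hits <- GenomicRanges::findOverlaps(tx_gr, frag_gr)
  idx <- split(S4Vectors::subjectHits(hits),
               factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(transcripts))))
  fragment_idx <- lapply(idx, function(i) sort(as.integer(i)))
  names(fragment_idx) <- transcripts$transcript_id
  excluded <- transcripts$transcript_id[lengths(fragment_idx) == 0L]
  structure(list(
    transcripts = transcripts[, c("transcript_id", "gene_id")],
    fragment_idx = fragment_idx[lengths(fragment_idx) > 0L],
    excluded = excluded,
    map = fragment_map
  ), class = "fragment_assignment")
}

#' @export
print.fragment_assignment <- function(x, ...) {
  cat(sprintf(
    "Fragment assignment: %d transcript(s), %d gene(s), %d excluded (0 fragments)\n",
    length(x$fragment_idx), length(unique(x$transcripts$gene_id)),
    length(x$excluded)))
  invisible(x)
}

#' Union of fragment indices over all transcripts of a gene
#'
#' @param assignment A \code{fragment_assignment}.
#' @param gene_id Single gene identifier.
#' @return Sorted integer vector of map row indices.
#' @export
gene_fragment_union <- function(assignment, gene_id) {
  stopifnot(inherits(assignment, "fragment_assignment"), length(gene_id) == 1L)
  tx <- assignment$transcripts$transcript_id[
    assignment$transcripts$gene_id == gene_id]
  tx <- intersect(tx, names(assignment$fragment_idx))
  if (length(tx) == 0L) {
    stop("gene '", gene_id, "' has no assigned fragments")
  }
  sort(unique(unlist(assignment$fragment_idx[tx], use.names = FALSE)))
}
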