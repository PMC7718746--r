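#' Length-weighted mean occupancy per transcript
#'
#' For each transcript the mean occupancy is the fragment-length-weighted
#' mean of the track values over its assigned fragments. Transcripts with
#' fewer than \code{min_fragments} fragments are excluded (a 1-fragment mean
#' involves no averaging) and listed in the \code{excluded} attribute.
#'
#' @param track A \code{ratio_track}.
#' @param assignment A \code{fragment_assignment} on the same map.
#' @param min_fragments Minimum fragments per transcript (default 2).
#' @return data.frame with \code{transcript_id}, \code{gene_id},
#'   \code{n_fragments}, \code{mean_occupancy}; attribute \code{excluded}
#'   lists transcripts dropped for having too few fragments (plus those with
#'   none at all).
#' @export
transcript_occupancy <- function(track, assignment, min_fragments = 2L) {
  stopifnot(inherits(track, "ratio_track"),
            inherits(assignment, "fragment_assignment"))
  stop_if_map_mismatch(track$map, assignment$map, "track and assignment")
  if (length(assignment$fragment_idx) == 0L) {
    warning("empty assignment: no transcripts to score")
    out <- data.frame(transcript_id = character(0), gene_id = character(0),
                      n_fragments = integer(0), mean_occupancy = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "excluded") <- assignment$excluded
    return(out)
  }
  len <- track$map$end - track$map$start
  ids <- names(assignment$fragment_idx)
  nf <- lengths(assignment$fragment_idx)
  keep <- nf >= min_fragments
  mo <- vapply(assignment$fragment_idx[keep], function(idx) {
    sum(len[idx] * track$value[idx]) / sum(len[idx])
  }, numeric(1))
  out <- data.frame(
    transcript_id = ids[keep],
    gene_id = assignment$transcripts$gene_id[
      match(ids[keep], assignment$transcripts$transcript_id)],
    n_fragments = unname(nf[keep]),
    mean_occupancy = unname(mo),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(assignment$excluded, ids[!keep])
  attr(out, "min_fragments") <- min_fragments
  out
}

# Permutation engine: for each transcript skeleton, the null statistic is the
# length-weighted mean of the (length, value) pairs landing on the skeleton
# after a genome-wide shuffle of the pairs. Returns the count of permutations
# with null mean >= observed mean (one-sided enrichment).
perm_exceed_counts <- function(values, lengths, idx_list, observed, n_perm,
                               permutations = NULL, chunk = 250L) {
  n <- length(values)
  nt <- length(idx_list)
  A <- Matrix::sparseMatrix(
    i = rep.int(seq_len(nt), lengths(idx_list)),
    j = unlist(idx_list, use.names = FALSE),
    x = 1, dims = c(nt, n))
  lv <- lengths * values
  exceed <- integer(nt)
  eps <- 1e-12
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    if (is.null(permutations)) {
      P <- vapply(seq_len(m), function(i) sample.int(n), integer(n))
    } else {
      P <- permutations[, (done + 1L):(done + m), drop = FALSE]
    }
    num <- as.matrix(A %*% matrix(lv[P], nrow = n))
    den <- as.matrix(A %*% matrix(lengths[P], nrow = n))
    exceed <- exceed + rowSums((num / den) >= (observed - eps))
    done <- done + m
  }
  exceed
}

#' Empirical occupancy significance with permutation FDR
#'
#' Tests, per transcript, whether its length-weighted mean occupancy exceeds
#' what a genome-wide shuffle of (fragment length, value) pairs produces on
#' the same fragment skeleton (one-sided, enrichment). The empirical p-value
#' uses add-one smoothing, \code{p = (1 + #\{perm >= obs\}) / (1 + n_perm)},
#' so p is never 0; Benjamini-Hochberg adjustment yields the FDR and
#' \code{significant} flags transcripts with \code{fdr < alpha}.
#'
#' @param track A \code{ratio_track}.
#' @param assignment A \code{fragment_assignment} on the same map.
#' @param n_perm Number of permutations (>= 100; the resolution needed for
#'   alpha = 0.01). Ignored when \code{permutations} is supplied.
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance threshold on the FDR (default 0.01).
#' @param min_fragments Passed to \code{\link{transcript_occupancy}}.
#' @param permutations Optional explicit permutation matrix (one permutation
#'   of \code{1:n_fragments} per column), e.g. an exhaustive enumeration on a
#'   toy genome; overrides \code{n_perm} and the seed.
#' @return \code{occupancy_table}: the \code{\link{transcript_occupancy}}
#'   columns plus \code{p_emp}, \code{fdr}, \code{significant}; attributes
#'   \code{alpha}, \code{excluded}, and the track's \code{sample_kind} /
#'   \code{genotype}.
#' @export
occupancy_significance <- function(track, assignment, n_perm = 1000L,
                                   seed = 1L, alpha = 0.01,
                                   min_fragments = 2L, permutations = NULL) {
  if (is.null(permutations)) {
    if (n_perm < 100L) {
      stop("n_perm < 100: p-value resolution too coarse for alpha = 0.01")
    }
  } else {
    stopifnot(is.matrix(permutations),
              nrow(permutations) == nrow(track$map))
    n_perm <- ncol(permutations)
  }
  occ <- transcript_occupancy(track, assignment, min_fragments)
  if (nrow(occ) == 0L) {
    occ$p_emp <- numeric(0); occ$fdr <- numeric(0); occ$significant <- logical(0)
    attr(occ, "alpha") <- alpha
    class(occ) <- c("occupancy_table", "data.frame")
    return(occ)
  }
  len <- track$map$end - track$map$start
  set.seed(seed)
  exceed <- perm_exceed_counts(track$value, len,
                               assignment$fragment_idx[occ$transcript_id],
                               occ$mean_occupancy, n_perm, permutations)
  occ$p_emp <- (1 + exceed) / (1 + n_perm)
  occ$fdr <- stats::p.adjust(occ$p_emp, method = "BH")
  occ$significant <- occ$fdr < alpha
  attr(occ, "alpha") <- alpha
  attr(occ, "seed") <- seed
  attr(occ, "n_perm") <- n_perm
  attr(occ, "sample_kind") <- track$sample_kind
  attr(occ, "genotype") <- track$genotype
  class(occ) <- c("occupancy_table", "data.frame")
  occ
}

#' Reduce a transcript occupancy table to one row per gene
#'
#' Each gene is represented by its transcript with the most significant FDR;
#' ties are broken by larger \code{n_fragments}, then lexicographic
#' \code{transcript_id}.
#'
#' @param table An \code{occupancy_table} from
#'   \code{\link{occupancy_significance}}.
#' @return \code{gene_occupancy_table}: one row per gene, same columns,
#'   genotype/alpha attributes carried over.
#' @export
gene_table_from_transcripts <- function(table) {
  stopifnot(inherits(table, "occupancy_table"))
  ord <- order(table$fdr, -table$n_fragments, table$transcript_id)
  tab <- table[ord, , drop = FALSE]
  out <- tab[!duplicated(tab$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- attr(table, "alpha")
  attr(out, "sample_kind") <- attr(table, "sample_kind")
  attr(out, "genotype") <- attr(table, "genotype")
  class(out) <- c("gene_occupancy_table", "data.frame")
  out
}

#' Genes called significantly occupied
#'
#' @param gene_table A \code{gene_occupancy_table}.
#' @return Character vector of significant gene ids.
#' @export
significant_genes <- function(gene_table) {
  stopifnot(inherits(gene_table, "gene_occupancy_table"))
  gene_table$gene_id[gene_table$significant]
}
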