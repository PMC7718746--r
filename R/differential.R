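#' Replicate-wise difference tracks between genotypes
#'
#' Subtracts control from knockdown log2-ratio tracks fragment-wise, paired
#' by replicate index, producing one comparison track per replicate pair.
#' Tracks must be unscaled: the subtraction is on the raw log2-ratio axis.
#'
#' @param knockdown_reps,control_reps Lists of unscaled \code{ratio_track}s
#'   of equal length on the same map.
#' @return List of difference \code{ratio_track}s (genotype
#'   \code{"knockdown-control"}).
#' @export
difference_tracks <- function(knockdown_reps, control_reps) {
  stopifnot(is.list(knockdown_reps), is.list(control_reps))
  if (length(knockdown_reps) != length(control_reps)) {
    stop("unequal replicate counts: pairing undefined")
  }
  lapply(seq_along(knockdown_reps), function(i) {
    kd <- knockdown_reps[[i]]; ctl <- control_reps[[i]]
    stopifnot(inherits(kd, "ratio_track"), inherits(ctl, "ratio_track"))
    if (kd$scaled || ctl$scaled) {
      stop("difference tracks must be formed from unscaled tracks")
    }
    stop_if_map_mismatch(kd$map, ctl$map, "replicate pair")
    new_ratio_track(kd$map, kd$value - ctl$value,
                    sample_kind = kd$sample_kind,
                    genotype = "knockdown-control", replicate = i)
  })
}

#' Length-weighted mean of a track over a gene locus
#'
#' The locus value is the fragment-length-weighted mean of the track over
#' the union of the gene's transcript fragments.
#'
#' @param track A \code{ratio_track} (typically the replicate-averaged
#'   difference track).
#' @param gene_id Single gene identifier present in the assignment.
#' @param assignment A \code{fragment_assignment} on the same map.
#' @return The locus mean (scalar).
#' @export
locus_average_ratio <- function(track, gene_id, assignment) {
  stopifnot(inherits(track, "ratio_track"),
            inherits(assignment, "fragment_assignment"))
  stop_if_map_mismatch(track$map, assignment$map, "track and assignment")
  idx <- gene_fragment_union(assignment, gene_id)
  len <- track$map$end - track$map$start
  sum(len[idx] * track$value[idx]) / sum(len[idx])
}

#' Per-isoform length-weighted means of a track for one gene
#'
#' @inheritParams locus_average_ratio
#' @return Named numeric vector (one value per isoform with assigned
#'   fragments).
#' @export
isoform_ratios <- function(track, gene_id, assignment) {
  stopifnot(inherits(track, "ratio_track"),
            inherits(assignment, "fragment_assignment"))
  stop_if_map_mismatch(track$map, assignment$map, "track and assignment")
  tx <- assignment$transcripts$transcript_id[
    assignment$transcripts$gene_id == gene_id]
  tx <- intersect(tx, names(assignment$fragment_idx))
  if (length(tx) == 0L) stop("gene '", gene_id, "' has no assigned fragments")
  len <- track$map$end - track$map$start
  vapply(stats::setNames(tx, tx), function(t) {
    idx <- assignment$fragment_idx[[t]]
    sum(len[idx] * track$value[idx]) / sum(len[idx])
  }, numeric(1))
}

#' Call genes with significantly changed occupancy between genotypes
#'
#' The replicate difference tracks are averaged and the permutation
#' machinery of \code{\link{occupancy_significance}} is applied twice — once
#' for enrichment (up in knockdown) and once on the negated track for
#' depletion (down) — with Benjamini-Hochberg adjustment within each
#' direction. Per gene, the best transcript of the direction matching the
#' sign of its locus delta provides the FDR. Reported up-genes must
#' additionally be occupied in the knockdown genotype's own Pol II analysis
#' (the numerator filter: log2 ratios can be "significantly enriched" while
#' negative in both genotypes). Reported down-genes must pass the
#' fold-change threshold \code{|locus_delta| > log2(fc_threshold)}.
#'
#' @param diff_tracks Output of \code{\link{difference_tracks}}.
#' @param assignment A \code{fragment_assignment} on the same map.
#' @param numerator_gene_table \code{gene_occupancy_table} of the knockdown
#'   genotype's Pol II occupancy (its \code{genotype} attribute must be
#'   \code{"knockdown"}).
#' @param n_perm,seed,alpha,min_fragments Passed to
#'   \code{\link{occupancy_significance}}.
#' @param fc_threshold Fold-change threshold applied to down-genes
#'   (default 1.3).
#' @return \code{differential_table}: one row per scored gene, sorted by
#'   FDR, with \code{gene_id}, \code{locus_delta},
#'   \code{isoform_delta_best} (isoform with highest ratio),
#'   \code{direction}, \code{fdr}, \code{significant},
#'   \code{bound_in_numerator}, \code{passes_fc}, \code{reported},
#'   \code{excluded_reason}.
#' @export
differential_genes <- function(diff_tracks, assignment, numerator_gene_table,
                               n_perm = 1000L, seed = 1L, alpha = 0.01,
                               fc_threshold = 1.3, min_fragments = 2L) {
  stopifnot(is.list(diff_tracks), length(diff_tracks) >= 1L,
            inherits(assignment, "fragment_assignment"),
            inherits(numerator_gene_table, "gene_occupancy_table"))
  if (!identical(attr(numerator_gene_table, "genotype"), "knockdown")) {
    stop("numerator gene table must come from the knockdown genotype ",
         "(genotype attribute is '",
         attr(numerator_gene_table, "genotype"), "')")
  }
  avg <- average_tracks(diff_tracks)
  up_occ <- occupancy_significance(avg, assignment, n_perm = n_perm,
                                   seed = seed, alpha = alpha,
                                   min_fragments = min_fragments)
  # the same permutation stream serves both one-sided tests, making the
  # analysis exactly antisymmetric under swapping the genotypes
  neg <- avg; neg$value <- -neg$value
  down_occ <- occupancy_significance(neg, assignment, n_perm = n_perm,
                                     seed = seed, alpha = alpha,
                                     min_fragments = min_fragments)
  up_gene <- gene_table_from_transcripts(up_occ)
  down_gene <- gene_table_from_transcripts(down_occ)
  genes <- sort(unique(up_gene$gene_id))
  locus_delta <- vapply(genes, function(g) locus_average_ratio(avg, g, assignment),
                        numeric(1))
  iso_best <- vapply(genes, function(g) max(isoform_ratios(avg, g, assignment)),
                     numeric(1))
  direction <- ifelse(locus_delta > 0, "up", "down")
  fdr <- ifelse(direction == "up",
                up_gene$fdr[match(genes, up_gene$gene_id)],
                down_gene$fdr[match(genes, down_gene$gene_id)])
  numerator_sig <- significant_genes(numerator_gene_table)
  bound <- genes %in% numerator_sig
  passes_fc <- ifelse(direction == "down",
                      abs(locus_delta) > log2(fc_threshold), TRUE)
  significant <- fdr < alpha
  reported <- significant &
    ifelse(direction == "up", bound, passes_fc)
  excluded_reason <- rep(NA_character_, length(genes))
  excluded_reason[significant & direction == "up" & !bound] <-
    "not_bound_in_numerator"
  excluded_reason[significant & direction == "down" & !passes_fc] <-
    "below_fc_threshold"
  out <- data.frame(gene_id = genes, locus_delta = unname(locus_delta),
                    isoform_delta_best = unname(iso_best),
                    direction = direction, fdr = unname(fdr),
                    significant = significant, bound_in_numerator = bound,
                    passes_fc = passes_fc, reported = reported,
                    excluded_reason = excluded_reason,
                    stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "n_perm") <- n_perm
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Reported up-regulated (de-repressed) genes
#' @param dt A \code{differential_table}.
#' @return Character vector of gene ids.
#' @export
up_genes <- function(dt) {
  stopifnot(inherits(dt, "differential_table"))
  dt$gene_id[dt$reported & dt$direction == "up"]
}

#' Reported down-regulated genes
#' @param dt A \code{differential_table}.
#' @return Character vector of gene ids.
#' @export
down_genes <- function(dt) {
  stopifnot(inherits(dt, "differential_table"))
  dt$gene_id[dt$reported & dt$direction == "down"]
}
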