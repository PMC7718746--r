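#' Gene-level occupancy on a scaled, averaged Dam-Pc track
#'
#' The Polycomb loss filter's occupancy threshold of 1 is defined on the
#' SD-scaled, replicate-averaged axis, so this function refuses unscaled or
#' unaveraged input rather than silently producing values on the wrong
#' scale.
#'
#' @param scaled_avg_pc_track A \code{ratio_track} with \code{scaled} and
#'   \code{averaged} both \code{TRUE}.
#' @param assignment A \code{fragment_assignment} on the same map.
#' @return Named numeric vector: length-weighted mean over each gene's
#'   fragment union, for every gene with assigned fragments.
#' @export
pc_gene_occupancy <- function(scaled_avg_pc_track, assignment) {
  stopifnot(inherits(scaled_avg_pc_track, "ratio_track"),
            inherits(assignment, "fragment_assignment"))
  if (!scaled_avg_pc_track$scaled) {
    stop("Pc occupancy threshold is defined on the SD-scaled axis: ",
         "scale the track with scale_by_sd() first")
  }
  if (!scaled_avg_pc_track$averaged) {
    stop("Pc occupancy requires the replicate-averaged track ",
         "(average_tracks())")
  }
  stop_if_map_mismatch(scaled_avg_pc_track$map, assignment$map,
                       "track and assignment")
  genes <- unique(assignment$transcripts$gene_id[
    assignment$transcripts$transcript_id %in% names(assignment$fragment_idx)])
  vapply(stats::setNames(genes, genes), function(g) {
    locus_average_ratio(scaled_avg_pc_track, g, assignment)
  }, numeric(1))
}

#' Polycomb binding-loss gene filter
#'
#' A gene passes iff it has significant Dam-Pc occupancy in control,
#' significant Dam-Pol II occupancy in both genotypes, and its scaled Dam-Pc
#' occupancy is above 1 in control and below 1 in the knockdown.
#'
#' @param pc_ctl_occ,pc_kd_occ Named gene-level occupancy vectors from
#'   \code{\link{pc_gene_occupancy}} for control and knockdown (identical
#'   gene universes).
#' @param pc_sig_ctl Character vector of genes with significant Dam-Pc
#'   occupancy in control (e.g. \code{\link{significant_genes}} of the
#'   control Pc analysis).
#' @param polII_ctl,polII_kd \code{gene_occupancy_table}s of Dam-Pol II
#'   occupancy for control and knockdown (checked via their \code{genotype}
#'   attributes when set).
#' @param threshold Occupancy threshold on the scaled axis (default 1).
#' @return data.frame, one row per gene sorted by control Pc occupancy
#'   descending: \code{gene_id}, \code{pc_occ_control},
#'   \code{pc_occ_knockdown}, \code{pc_significant_control},
#'   \code{polII_significant_control}, \code{polII_significant_knockdown},
#'   \code{passes}.
#' @export
pc_loss_filter <- function(pc_ctl_occ, pc_kd_occ, pc_sig_ctl,
                           polII_ctl, polII_kd, threshold = 1) {
  stopifnot(inherits(polII_ctl, "gene_occupancy_table"),
            inherits(polII_kd, "gene_occupancy_table"))
  for (chk in list(list(polII_ctl, "control"), list(polII_kd, "knockdown"))) {
    g <- attr(chk[[1]], "genotype")
    if (!is.null(g) && !is.na(g) && !identical(g, chk[[2]])) {
      stop("Pol II gene table labelled '", g, "' supplied where '",
           chk[[2]], "' was expected")
    }
  }
  universe <- names(pc_ctl_occ)
  if (!setequal(universe, names(pc_kd_occ))) {
    stop("gene-id mismatch between control and knockdown Pc occupancy: ",
         paste(union(setdiff(universe, names(pc_kd_occ)),
                     setdiff(names(pc_kd_occ), universe)), collapse = ", "))
  }
  strays <- unique(c(setdiff(pc_sig_ctl, universe),
                     setdiff(polII_ctl$gene_id, universe),
                     setdiff(polII_kd$gene_id, universe)))
  if (length(strays) > 0L) {
    stop("gene id(s) outside the annotation universe: ",
         paste(strays, collapse = ", "))
  }
  out <- data.frame(
    gene_id = universe,
    pc_occ_control = unname(pc_ctl_occ[universe]),
    pc_occ_knockdown = unname(pc_kd_occ[universe]),
    pc_significant_control = universe %in% pc_sig_ctl,
    polII_significant_control = universe %in% significant_genes(polII_ctl),
    polII_significant_knockdown = universe %in% significant_genes(polII_kd),
    stringsAsFactors = FALSE)
  out$passes <- out$pc_significant_control &
    out$polII_significant_control & out$polII_significant_knockdown &
    out$pc_occ_control > threshold & out$pc_occ_knockdown < threshold
  out <- out[order(-out$pc_occ_control, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

#' Mean Pc binding of a gene set
#'
#' Ranked table of scaled Dam-Pc occupancy (length-weighted gene means) for
#' a set of genes of interest, e.g. the de-repressed gene list.
#'
#' @param gene_set Character vector of gene ids.
#' @param scaled_avg_pc_track Scaled, averaged Dam-Pc \code{ratio_track}.
#' @param assignment A \code{fragment_assignment}.
#' @return data.frame (\code{gene_id}, \code{mean_pc_binding}) sorted
#'   descending; empty with a warning for an empty gene set.
#' @export
mean_pc_binding <- function(gene_set, scaled_avg_pc_track, assignment) {
  if (length(gene_set) == 0L) {
    warning("empty gene set")
    return(data.frame(gene_id = character(0), mean_pc_binding = numeric(0),
                      stringsAsFactors = FALSE))
  }
  occ <- pc_gene_occupancy(scaled_avg_pc_track, assignment)
  missing <- setdiff(gene_set, names(occ))
  if (length(missing) > 0L) {
    stop("gene(s) not present in assignment: ", paste(missing, collapse = ", "))
  }
  out <- data.frame(gene_id = gene_set,
                    mean_pc_binding = unname(occ[gene_set]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_pc_binding, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
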