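#' Run the full DamID differential pipeline on simulated data
#'
#' Orchestrates every stage against a synthetic experiment: GATC digestion
#' and fragment-transcript assignment, per-replicate log2(fusion/Dam) ratio
#' tracks, per-genotype Pol II occupancy calling on the replicate-averaged
#' track, replicate-wise genotype subtraction with differential calling and
#' the numerator filter, and (when Dam-Pc samples are simulated) the
#' Polycomb binding-loss filter on SD-scaled, averaged Pc tracks.
#'
#' @param config A \code{\link{sim_config}}.
#' @param n_perm Permutations for all significance calls. The default 4000
#'   keeps the empirical p-value floor (1/(n_perm+1)) far enough below the
#'   Benjamini-Hochberg bar that an FDR of 0.01 is attainable when a few
#'   hundred transcripts are tested.
#' @param seed Seed for the permutation streams (distinct offsets per call);
#'   defaults to the simulation seed.
#' @param alpha FDR threshold (default 0.01).
#' @param fc_threshold Fold-change threshold for down-genes (default 1.3).
#' @param pseudocount Ratio-track pseudocount.
#' @param sample_kinds Fusion kinds to simulate; must include
#'   \code{"Dam"} and \code{"Dam-PolII"}; add \code{"Dam-Pc"} for the
#'   Polycomb filter.
#' @return List: \code{sim} (the simulated experiment), \code{assignment},
#'   \code{tracks[[genotype]][[kind]]} (list of replicate ratio tracks),
#'   \code{replicate_r} (per genotype/kind pairwise Pearson r),
#'   \code{polII_transcripts} and \code{polII_genes} per genotype,
#'   \code{differential} (a \code{differential_table}), and when Pc samples
#'   are present \code{pc_tracks}, \code{pc_filter} and \code{pc_occupancy}.
#' @export
run_damid_pipeline <- function(config = sim_config(), n_perm = 4000L,
                               seed = config$seed, alpha = 0.01,
                               fc_threshold = 1.3, pseudocount = 0.5,
                               sample_kinds = c("Dam", "Dam-PolII", "Dam-Pc")) {
  stopifnot(all(c("Dam", "Dam-PolII") %in% sample_kinds))
  sim <- simulate_experiment(config, sample_kinds)
  asn <- map_fragments_to_transcripts(sim$map, sim$annotation$transcripts)
  fusion_kinds <- setdiff(sample_kinds, "Dam")
  tracks <- list(); replicate_r <- list()
  for (geno in c("control", "knockdown")) {
    tracks[[geno]] <- list()
    for (kind in fusion_kinds) {
      tracks[[geno]][[kind]] <- lapply(seq_len(config$replicates), function(r) {
        compute_ratio_track(sim$counts[[geno]][[kind]][[r]],
                            sim$counts[[geno]][["Dam"]][[r]], sim$map,
                            pseudocount = pseudocount, sample_kind = kind,
                            genotype = geno, replicate = r)
      })
      reps <- tracks[[geno]][[kind]]
      prs <- utils::combn(length(reps), 2L)
      replicate_r[[paste(geno, kind, sep = ".")]] <- apply(prs, 2L, function(ij) {
        replicate_correlation(reps[[ij[1]]], reps[[ij[2]]])
      })
    }
  }
  polII_tx <- list(); polII_genes <- list()
  for (geno in c("control", "knockdown")) {
    avg <- average_tracks(tracks[[geno]][["Dam-PolII"]])
    occ <- occupancy_significance(avg, asn, n_perm = n_perm,
                                  seed = seed + match(geno, c("control", "knockdown")),
                                  alpha = alpha)
    polII_tx[[geno]] <- occ
    polII_genes[[geno]] <- gene_table_from_transcripts(occ)
  }
  diffs <- difference_tracks(tracks[["knockdown"]][["Dam-PolII"]],
                             tracks[["control"]][["Dam-PolII"]])
  differential <- differential_genes(diffs, asn, polII_genes[["knockdown"]],
                                     n_perm = n_perm, seed = seed + 10L,
                                     alpha = alpha, fc_threshold = fc_threshold)
  out <- list(sim = sim, assignment = asn, tracks = tracks,
              replicate_r = replicate_r, polII_transcripts = polII_tx,
              polII_genes = polII_genes, differential = differential)
  if ("Dam-Pc" %in% sample_kinds) {
    pc_scaled_avg <- lapply(tracks, function(tr) {
      average_tracks(lapply(tr[["Dam-Pc"]], scale_by_sd))
    })
    pc_sig_ctl <- significant_genes(gene_table_from_transcripts(
      occupancy_significance(pc_scaled_avg[["control"]], asn, n_perm = n_perm,
                             seed = seed + 20L, alpha = alpha)))
    pc_ctl_occ <- pc_gene_occupancy(pc_scaled_avg[["control"]], asn)
    pc_kd_occ <- pc_gene_occupancy(pc_scaled_avg[["knockdown"]], asn)
    out$pc_tracks <- pc_scaled_avg
    out$pc_occupancy <- list(control = pc_ctl_occ, knockdown = pc_kd_occ)
    out$pc_filter <- pc_loss_filter(pc_ctl_occ, pc_kd_occ, pc_sig_ctl,
                                    polII_genes[["control"]],
                                    polII_genes[["knockdown"]])
  }
  out
}
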