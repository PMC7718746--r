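tadadiff_extdata <- function(file) {
  path <- system.file("extdata", file, package = "tadadiff")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Packaged adult wing-eversion phenotype table (percentages)
#'
#' Transcription of the published adult eversion outcomes for knockdowns of
#' the Polycomb-group genes Sce and Scm under three peripodial GAL4 drivers:
#' per genotype, the printed percentage of adults in each severity category
#' (normal, weak, strong, early-lethal) and the number scored.
#'
#' @param as_counts If TRUE (default) reconstruct integer counts and return
#'   a \code{phenotype_table}; otherwise return the raw percentage table.
#' @return A \code{phenotype_table} or data.frame.
#' @export
load_eversion_table <- function(as_counts = TRUE) {
  df <- utils::read.csv(tadadiff_extdata("eversion_phenotypes_pct.csv"),
                        stringsAsFactors = FALSE)
  if (!as_counts) return(df)
  phenotype_from_percentages(df, c("normal", "weak", "strong", "early_lethal"))
}

#' Packaged eversion-rescue phenotype table (percentages)
#'
#' Transcription of the published rescue experiment: eversion outcomes when
#' the Sce knockdown is combined with RNAi against each of the four
#' de-repressed genes (Abd-B, abd-A, cad, nub) or a GFP control, over six
#' severity categories.
#'
#' @inheritParams load_eversion_table
#' @return A \code{phenotype_table} or data.frame.
#' @export
load_rescue_table <- function(as_counts = TRUE) {
  df <- utils::read.csv(tadadiff_extdata("rescue_phenotypes_pct.csv"),
                        stringsAsFactors = FALSE)
  if (!as_counts) return(df)
  phenotype_from_percentages(
    df, c("normal", "crumpled", "cleft", "single", "double", "lethal"))
}

#' Packaged de-repressed gene table
#'
#' Transcription of the published list of 17 genes significantly gaining
#' Pol II occupancy in the knockdown: symbol, name, locus log2 ratio (best
#' transcript isoform) and FDR.
#'
#' @return data.frame with \code{symbol}, \code{name}, \code{ratio},
#'   \code{fdr}.
#' @export
load_derepressed_table <- function() {
  utils::read.csv(tadadiff_extdata("derepressed_genes.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged disc-culture assay proportions
#'
#' Transcription of the ex vivo disc-culture statistics: per assay
#' (overnight eversion, adherens-junction integrity, basement-membrane
#' integrity) and genotype, the printed success percentage, its printed
#' precision and the number of discs scored. Success counts are
#' reconstructed from the percentages.
#'
#' @return data.frame with \code{assay}, \code{genotype}, \code{percent},
#'   \code{n}, \code{successes}, \code{p_printed}.
#' @export
load_disc_culture_table <- function() {
  df <- utils::read.csv(tadadiff_extdata("disc_culture_pct.csv"),
                        stringsAsFactors = FALSE)
  df$successes <- mapply(function(p, n, d) counts_from_percentages(p, n, d),
                         df$percent, df$n, df$digits)
  df
}
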