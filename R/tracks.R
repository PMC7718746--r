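#' Construct a ratio track object
#'
#' Internal constructor; users normally obtain tracks from
#' \code{\link{compute_ratio_track}} or \code{\link{read_ratio_bedgraph}}.
#'
#' @param map A \code{gatc_map}.
#' @param value Numeric vector, one finite value per fragment.
#' @param sample_kind,genotype,replicate Metadata (free-form).
#' @param scaled Has the track been divided by its population SD?
#' @param averaged Is the track a replicate average?
#' @return A \code{ratio_track}.
#' @keywords internal
new_ratio_track <- function(map, value, sample_kind = NA_character_,
                            genotype = NA_character_, replicate = NA,
                            scaled = FALSE, averaged = FALSE) {
  stopifnot(inherits(map, "gatc_map"), length(value) == nrow(map),
            all(is.finite(value)))
  structure(list(map = map, value = as.numeric(value),
                 sample_kind = sample_kind, genotype = genotype,
                 replicate = replicate, scaled = isTRUE(scaled),
                 averaged = isTRUE(averaged)),
            class = "ratio_track")
}

#' @export
print.ratio_track <- function(x, ...) {
  cat(sprintf(
    "Ratio track [%s / %s / rep %s]: %d fragments, mean %.3f, sd %.3f%s%s\n",
    x$sample_kind, x$genotype, paste(x$replicate, collapse = "+"),
    length(x$value), mean(x$value), stats::sd(x$value),
    if (x$scaled) ", scaled" else "", if (x$averaged) ", averaged" else ""))
  invisible(x)
}

#' Per-fragment log2(Dam-fusion / Dam) ratio track
#'
#' Both samples are first equalized to reads-per-million, then a pseudocount
#' is added to numerator and denominator so every fragment has a finite log2
#' ratio: \code{log2((fusion_i * s_f + pc) / (dam_i * s_d + pc))} with
#' \code{s = 1e6 / total}. Applying the pseudocount after depth scaling keeps
#' the zero-count floor independent of sequencing depth. The result is
#' invariant to rescaling either sample's counts by a positive constant.
#'
#' @param fusion_counts,dam_counts Non-negative integer count vectors aligned
#'   to \code{map}, with positive totals.
#' @param map The shared \code{gatc_map}.
#' @param pseudocount Non-negative real, default 0.5.
#' @param sample_kind,genotype,replicate Metadata stored on the track.
#' @return An unscaled \code{ratio_track}.
#' @examples
#' g <- c(chrA = "AAGATCAA")
#' m <- build_fragment_map(g)
#' compute_ratio_track(c(8, 2), c(2, 8), m)
#' @export
compute_ratio_track <- function(fusion_counts, dam_counts, map,
                                pseudocount = 0.5,
                                sample_kind = NA_character_,
                                genotype = NA_character_, replicate = NA) {
  stopifnot(inherits(map, "gatc_map"), pseudocount >= 0)
  if (length(fusion_counts) != nrow(map) || length(dam_counts) != nrow(map)) {
    stop("count vectors do not match the fragment map")
  }
  if (any(fusion_counts < 0) || any(dam_counts < 0)) {
    stop("negative counts are not allowed")
  }
  tf <- sum(fusion_counts); td <- sum(dam_counts)
  if (tf <= 0 || td <= 0) stop("count totals must be positive")
  sf <- 1e6 / tf; sd_ <- 1e6 / td
  value <- log2((fusion_counts * sf + pseudocount) /
                  (dam_counts * sd_ + pseudocount))
  new_ratio_track(map, value, sample_kind = sample_kind, genotype = genotype,
                  replicate = replicate)
}

#' Pearson correlation of two replicate tracks over fragments
#'
#' Unweighted correlation of per-fragment values; the replicate-concordance
#' statistic reported for DamID experiments.
#'
#' @param track_a,track_b \code{ratio_track}s on the same map with at least
#'   3 fragments and nonzero variance.
#' @return Pearson r in \[-1, 1\].
#' @export
replicate_correlation <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "ratio_track"), inherits(track_b, "ratio_track"))
  stop_if_map_mismatch(track_a$map, track_b$map, "tracks")
  if (length(track_a$value) < 3L) stop("need at least 3 fragments")
  if (stats::sd(track_a$value) == 0 || stats::sd(track_b$value) == 0) {
    stop("zero-variance track: correlation undefined")
  }
  stats::cor(track_a$value, track_b$value)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Scale a track by its population standard deviation
#'
#' Divides every fragment value by the population (1/n) standard deviation of
#' the whole track, unweighted by fragment length, and sets the
#' \code{scaled} flag. Idempotent after the first application.
#'
#' @param track A \code{ratio_track} with nonzero variance.
#' @return The scaled track (population SD exactly 1).
#' @export
scale_by_sd <- function(track) {
  stopifnot(inherits(track, "ratio_track"))
  s <- pop_sd(track$value)
  if (s < 1e-12) stop("zero-variance track cannot be scaled")
  track$value <- track$value / s
  track$scaled <- TRUE
  track
}

#' Fragment-wise average of replicate tracks
#'
#' @param tracks Non-empty list of \code{ratio_track}s on the same map and
#'   with the same \code{scaled} flag.
#' @return A \code{ratio_track} with \code{averaged = TRUE}; its
#'   \code{replicate} field records the input replicates.
#' @export
average_tracks <- function(tracks) {
  stopifnot(is.list(tracks), length(tracks) >= 1L,
            all(vapply(tracks, inherits, logical(1), "ratio_track")))
  for (t in tracks[-1]) {
    stop_if_map_mismatch(tracks[[1]]$map, t$map, "tracks")
    if (t$scaled != tracks[[1]]$scaled) {
      stop("cannot average scaled with unscaled tracks")
    }
  }
  vals <- rowMeans(do.call(cbind, lapply(tracks, `[[`, "value")))
  new_ratio_track(tracks[[1]]$map, vals,
                  sample_kind = tracks[[1]]$sample_kind,
                  genotype = tracks[[1]]$genotype,
                  replicate = unlist(lapply(tracks, `[[`, "replicate")),
                  scaled = tracks[[1]]$scaled, averaged = TRUE)
}
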