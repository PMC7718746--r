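# One simulated world with a real effect, reused across several blocks.
diff_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- tiny_config(effect_size = 1.5)
      sim <- simulate_experiment(cfg, sample_kinds = c("Dam", "Dam-PolII"))
      asn <- map_fragments_to_transcripts(sim$map, sim$annotation$transcripts)
      tr <- function(geno) lapply(1:2, function(r) {
        compute_ratio_track(sim$counts[[geno]][["Dam-PolII"]][[r]],
                            sim$counts[[geno]][["Dam"]][[r]], sim$map,
                            sample_kind = "Dam-PolII", genotype = geno,
                            replicate = r)
      })
      kd <- tr("knockdown"); ctl <- tr("control")
      num <- gene_table_from_transcripts(occupancy_significance(
        average_tracks(kd), asn, n_perm = 500L, seed = 9L))
      cache <<- list(sim = sim, asn = asn, kd = kd, ctl = ctl, numerator = num)
    }
    cache
  }
})

test_that("difference tracks subtract fragment-wise, paired by replicate", {
  w <- diff_world()
  d <- difference_tracks(w$kd, w$ctl)
  expect_length(d, 2L)
  for (i in 1:2) {
    expect_equal(d[[i]]$value, w$kd[[i]]$value - w$ctl[[i]]$value,
                 tolerance = 1e-12)
  }
  self <- difference_tracks(w$ctl, w$ctl)
  expect_equal(self[[1]]$value, rep(0, nrow(w$sim$map)))
  # 1.5 vs 0.5 on a fragment -> 1.0
  map <- map_with_lengths(c(10, 10))
  a <- toy_track(map, c(1.5, 0)); b <- toy_track(map, c(0.5, 0))
  expect_equal(difference_tracks(list(a), list(b))[[1]]$value[1], 1)
  expect_error(difference_tracks(w$kd, w$ctl[1]), "unequal replicate")
  expect_error(difference_tracks(list(scale_by_sd(a)), list(b)), "unscaled")
})

test_that("locus average ratio is the weighted mean over the gene fragment union", {
  w <- diff_world()
  avg <- average_tracks(difference_tracks(w$kd, w$ctl))
  len <- w$sim$map$end - w$sim$map$start
  for (g in utils::head(w$sim$annotation$genes$gene_id, 4L)) {
    idx <- gene_fragment_union(w$asn, g)
    expect_equal(locus_average_ratio(avg, g, w$asn),
                 sum(len[idx] * avg$value[idx]) / sum(len[idx]),
                 tolerance = 1e-12)
  }
  # constant and zero tracks
  map <- map_with_lengths(c(10, 20, 30))
  tx <- data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chrA",
                   start = 0L, end = 60L)
  asn <- map_fragments_to_transcripts(map, tx)
  expect_equal(locus_average_ratio(toy_track(map, rep(0.5, 3)), "g1", asn), 0.5)
  expect_equal(locus_average_ratio(toy_track(map, rep(0, 3)), "g1", asn), 0)
  expect_error(locus_average_ratio(toy_track(map, rep(0, 3)), "gZ", asn),
               "no assigned fragments")
})

test_that("differential calling recovers the simulated effect and respects filters", {
  w <- diff_world()
  dt <- differential_genes(difference_tracks(w$kd, w$ctl), w$asn, w$numerator,
                           n_perm = 2000L, seed = 4L)
  truth <- w$sim$truth
  dere <- truth$gene_id[truth$delta_polII_knockdown > 0]
  expect_true(all(dt$direction[dt$locus_delta > 0] == "up"))
  expect_true(all(dt$direction[dt$locus_delta <= 0] == "down"))
  up <- up_genes(dt)
  expect_gte(length(intersect(up, dere)), 2L)  # 3 truly de-repressed genes
  expect_length(setdiff(up, dere), 0L)
  # isoform-level deltas: best isoform >= locus average within float tolerance
  expect_true(all(dt$isoform_delta_best >= dt$locus_delta - 1e-9))
  # numerator filter semantics: a significant up-gene whose numerator call is
  # withdrawn must be excluded with a recorded reason
  num2 <- w$numerator
  num2$significant[num2$gene_id %in% up] <- FALSE
  dt2 <- differential_genes(difference_tracks(w$kd, w$ctl), w$asn, num2,
                            n_perm = 2000L, seed = 4L)
  expect_length(up_genes(dt2), 0L)
  expect_true(all(dt2$excluded_reason[dt2$gene_id %in% up] ==
                    "not_bound_in_numerator"))
  # wrong-genotype numerator table is refused
  bad <- w$numerator
  attr(bad, "genotype") <- "control"
  expect_error(differential_genes(difference_tracks(w$kd, w$ctl), w$asn, bad,
                                  n_perm = 200L), "knockdown")
})

test_that("swapping genotypes negates deltas and mirrors the calls exactly", {
  w <- diff_world()
  fwd <- differential_genes(difference_tracks(w$kd, w$ctl), w$asn,
                            w$numerator, n_perm = 500L, seed = 6L)
  rev <- differential_genes(difference_tracks(w$ctl, w$kd), w$asn,
                            w$numerator, n_perm = 500L, seed = 6L)
  m <- match(fwd$gene_id, rev$gene_id)
  expect_equal(rev$locus_delta[m], -fwd$locus_delta, tolerance = 1e-12)
  expect_identical(rev$direction[m],
                   ifelse(fwd$direction == "up", "down", "up"))
  expect_identical(rev$significant[m], fwd$significant)
  expect_equal(rev$fdr[m], fwd$fdr, tolerance = 1e-12)
})

test_that("a genotype-shared signal leaves the differential table unchanged", {
  w <- diff_world()
  shared <- rnorm(nrow(w$sim$map), sd = 0.5)
  shift <- function(tracks) lapply(tracks, function(t) {
    t$value <- t$value + shared; t
  })
  a <- differential_genes(difference_tracks(w$kd, w$ctl), w$asn, w$numerator,
                          n_perm = 300L, seed = 8L)
  b <- differential_genes(difference_tracks(shift(w$kd), shift(w$ctl)),
                          w$asn, w$numerator, n_perm = 300L, seed = 8L)
  expect_equal(a$locus_delta, b$locus_delta, tolerance = 1e-9)
  expect_identical(up_genes(a), up_genes(b))
  expect_identical(down_genes(a), down_genes(b))
})

test_that("down-gene fold-change gate uses log2(fc_threshold)", {
  # hand-built world: one clearly depleted gene below / above the gate
  lengths <- rep(10, 40)
  map <- map_with_lengths(lengths)
  tx <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                   chrom = "chrA", start = c(0L, 200L), end = c(60L, 260L))
  asn <- map_fragments_to_transcripts(map, tx)
  set.seed(121)
  base <- rnorm(40, sd = 0.05)
  mk <- function(delta1, delta2) {
    v <- base; v[1:6] <- v[1:6] + delta1; v[21:26] <- v[21:26] + delta2
    list(toy_track(map, v, genotype = "knockdown", replicate = 1),
         toy_track(map, v + rnorm(40, sd = 0.01), genotype = "knockdown",
                   replicate = 2))
  }
  ctl <- list(toy_track(map, rep(0, 40), genotype = "control", replicate = 1),
              toy_track(map, rep(0, 40), genotype = "control", replicate = 2))
  num <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
                    n_fragments = 6L, mean_occupancy = 1, p_emp = 0.001,
                    fdr = 0.001, significant = TRUE, stringsAsFactors = FALSE)
  class(num) <- c("gene_occupancy_table", "data.frame")
  attr(num, "genotype") <- "knockdown"
  # g1 down by 0.2 log2 (< log2(1.3) = 0.379): significant but gated out;
  # g2 down by 1.0 log2: reported
  dt <- differential_genes(difference_tracks(mk(-0.2, -1.0), ctl), asn, num,
                           n_perm = 500L, seed = 2L, alpha = 0.05)
  g1 <- dt[dt$gene_id == "g1", ]; g2 <- dt[dt$gene_id == "g2", ]
  expect_identical(g1$direction, "down")
  expect_false(g1$passes_fc)
  expect_true(g2$passes_fc)
  if (g1$significant) {
    expect_identical(g1$excluded_reason, "below_fc_threshold")
    expect_false(g1$reported)
  }
  expect_true(g2$reported)
})

test_that("sensitivity is monotone non-decreasing in effect size", {
  hits <- vapply(c(0.5, 1, 2), function(es) {
    cfg <- sim_config(seed = 3L, n_chromosomes = 2L,
                      chromosome_length = 150000L, n_genes = 30L,
                      n_derepressed = 6L, effect_size = es, library_size = 5e5,
                      gene_fragments = c(6L, 12L))
    sim <- simulate_experiment(cfg, sample_kinds = c("Dam", "Dam-PolII"))
    asn <- map_fragments_to_transcripts(sim$map, sim$annotation$transcripts)
    tr <- function(geno) lapply(1:2, function(r) {
      compute_ratio_track(sim$counts[[geno]][["Dam-PolII"]][[r]],
                          sim$counts[[geno]][["Dam"]][[r]], sim$map,
                          genotype = geno, replicate = r)
    })
    kd <- tr("knockdown")
    num <- gene_table_from_transcripts(occupancy_significance(
      average_tracks(kd), asn, n_perm = 1500L, seed = 5L))
    dt <- differential_genes(difference_tracks(kd, tr("control")), asn, num,
                             n_perm = 1500L, seed = 5L)
    dere <- sim$truth$gene_id[sim$truth$delta_polII_knockdown > 0]
    length(intersect(up_genes(dt), dere))
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
  expect_gt(hits[3], 0)
})
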