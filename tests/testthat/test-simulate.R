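test_that("config validation enforces the experimental design", {
  expect_error(sim_config(replicates = 1L))
  expect_error(sim_config(n_derepressed = 300L, n_genes = 200L))
  expect_error(sim_config(chromosome_length = 500L), "too few fragments")
  expect_error(sim_config(gatc_rate = 0.3))
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generate_genome is deterministic and honors gatc_rate = 0", {
  cfg0 <- tiny_config(gatc_rate = 0)
  g0 <- simulate_genome(cfg0)
  expect_identical(unname(lengths(g0$gatc_sites)), rep(0L, 2L))
  expect_false(any(grepl("GATC", g0$sequences, fixed = TRUE)))
  expect_identical(nrow(build_fragment_map(g0$sequences)), 2L)

  cfg <- tiny_config()
  expect_identical(simulate_genome(cfg), simulate_genome(cfg))
  cfg2 <- tiny_config(seed = 8L)
  expect_false(identical(simulate_genome(cfg)$sequences,
                         simulate_genome(cfg2)$sequences))
})

test_that("planted GATC density matches the configured rate (regex-scan oracle)", {
  cfg <- sim_config(seed = 1L, n_chromosomes = 1L, chromosome_length = 100000L,
                    gatc_rate = 1 / 256, n_genes = 10L, n_derepressed = 0L)
  g <- simulate_genome(cfg)
  scan <- find_gatc_sites(g$sequences[[1]])
  expect_identical(scan, g$gatc_sites[[1]])  # truth equals an independent scan
  expected <- 100000 / 256
  expect_lt(abs(length(scan) - expected), 4 * sqrt(expected))
})

test_that("generate_annotation produces nested, well-covered gene models with truth", {
  cfg <- tiny_config()
  genome <- simulate_genome(cfg)
  ann <- simulate_annotation(genome, cfg)
  expect_identical(nrow(ann$genes), cfg$n_genes)
  expect_identical(sort(ann$truth$gene_id), sort(ann$genes$gene_id))
  expect_false(anyDuplicated(ann$truth$gene_id) > 0)
  # transcripts nested in their gene, at least one isoform each
  m <- merge(ann$transcripts, ann$genes, by = c("gene_id", "chrom"),
             suffixes = c("", ".g"))
  expect_identical(nrow(m), nrow(ann$transcripts))
  expect_true(all(m$start >= m$start.g & m$end <= m$end.g))
  expect_true(all(table(ann$transcripts$gene_id) >= 1L))
  # every gene spans >= 5 GATC fragments
  asn <- map_fragments_to_transcripts(ann$map, ann$transcripts)
  nf <- vapply(ann$genes$gene_id,
               function(g) length(gene_fragment_union(asn, g)), integer(1))
  expect_true(all(nf >= 5L))
  # genes non-overlapping within a chromosome
  for (chr in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == chr, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # de-repression truth structure
  der <- ann$truth[ann$truth$delta_polII_knockdown > 0, ]
  expect_identical(nrow(der), cfg$n_derepressed)
  expect_true(all(der$pc_domain))
  expect_true(all(der$pc_occupancy_control > der$pc_occupancy_knockdown))
  expect_true(all(ann$truth$pc_occupancy_control >= 0))
  expect_true(all(ann$truth$pc_occupancy_knockdown >= 0))
  expect_true(all(ann$truth$delta_polII_knockdown[!ann$truth$pc_domain] == 0))
})

test_that("degenerate annotation designs work", {
  cfg <- tiny_config(n_genes = 0L, n_derepressed = 0L)
  ann <- simulate_annotation(simulate_genome(cfg), cfg)
  expect_identical(nrow(ann$transcripts), 0L)
  expect_identical(nrow(ann$truth), 0L)

  cfg2 <- tiny_config(n_derepressed = 0L)
  ann2 <- simulate_annotation(simulate_genome(cfg2), cfg2)
  expect_true(all(ann2$truth$delta_polII_knockdown == 0))

  cfg3 <- tiny_config(n_genes = 500L)
  expect_error(simulate_annotation(simulate_genome(cfg3), cfg3),
               "too small to place")
})

test_that("simulated counts are conserved, deterministic and validated", {
  cfg <- tiny_config()
  ann <- simulate_annotation(simulate_genome(cfg), cfg)
  cts <- simulate_damid_counts(ann, ann$map, ann$truth, "control",
                               "Dam-PolII", 1L, cfg)
  expect_type(cts, "integer")
  expect_true(all(cts >= 0L))
  expect_identical(sum(cts), as.integer(cfg$library_size))  # conservation
  expect_identical(cts, simulate_damid_counts(ann, ann$map, ann$truth,
                                              "control", "Dam-PolII", 1L, cfg))
  # distinct streams per genotype / kind / replicate
  expect_false(identical(cts, simulate_damid_counts(ann, ann$map, ann$truth,
                                                    "control", "Dam-PolII",
                                                    2L, cfg)))
  expect_false(identical(cts, simulate_damid_counts(ann, ann$map, ann$truth,
                                                    "knockdown", "Dam-PolII",
                                                    1L, cfg)))
  expect_error(simulate_damid_counts(ann, ann$map, ann$truth, "mutant",
                                     "Dam-PolII", 1L, cfg))
  expect_error(simulate_damid_counts(ann, ann$map, ann$truth, "control",
                                     "Dam-H1", 1L, cfg))
})

test_that("null signal at zero dispersion gives ratios centered on 0", {
  cfg <- tiny_config(n_derepressed = 0L, frac_expressed = 0, dispersion = 0,
                     library_size = 1e6)
  ann <- simulate_annotation(simulate_genome(cfg), cfg)
  fus <- simulate_damid_counts(ann, ann$map, ann$truth, "control",
                               "Dam-PolII", 1L, cfg)
  dam <- simulate_damid_counts(ann, ann$map, ann$truth, "control",
                               "Dam", 1L, cfg)
  track <- compute_ratio_track(fus, dam, ann$map)
  expect_lt(abs(mean(track$value)), 0.02)
  expect_lt(stats::sd(track$value), 0.2)
})

test_that("a +2 log2 knockdown effect quadruples the fusion/Dam ratio (Monte-Carlo oracle)", {
  # one small de-repressed gene in a large genome keeps the compositional
  # renormalization of the fixed library size below ~3%
  cfg <- sim_config(seed = 5L, n_chromosomes = 1L, chromosome_length = 500000L,
                    n_genes = 8L, n_derepressed = 1L, effect_size = 2,
                    frac_expressed = 0, gene_fragments = c(5L, 7L),
                    library_size = 1e6)
  ann <- simulate_annotation(simulate_genome(cfg), cfg)
  asn <- map_fragments_to_transcripts(ann$map, ann$transcripts)
  der <- ann$truth$gene_id[ann$truth$delta_polII_knockdown > 0]
  idx <- gene_fragment_union(asn, der)
  one_ratio <- function(geno, r) {
    fus <- simulate_damid_counts(ann, ann$map, ann$truth, geno, "Dam-PolII",
                                 r, cfg)
    dam <- simulate_damid_counts(ann, ann$map, ann$truth, geno, "Dam", r, cfg)
    sum(fus[idx]) / sum(dam[idx])
  }
  n_sim <- 50L
  r_kd <- mean(vapply(seq_len(n_sim), function(r) one_ratio("knockdown", r),
                      numeric(1)))
  r_ctl <- mean(vapply(seq_len(n_sim), function(r) one_ratio("control", r),
                       numeric(1)))
  expect_gt(r_kd / r_ctl, 4 * 0.85)
  expect_lt(r_kd / r_ctl, 4 * 1.15)
})

test_that("replicate ratio tracks at default dispersion correlate in the reported band", {
  cfg <- sim_config(seed = 2L, n_chromosomes = 2L, chromosome_length = 300000L,
                    n_genes = 60L, n_derepressed = 6L, library_size = 8e5)
  sim <- simulate_experiment(cfg, sample_kinds = c("Dam", "Dam-PolII"))
  tr <- lapply(1:2, function(r) {
    compute_ratio_track(sim$counts$control[["Dam-PolII"]][[r]],
                        sim$counts$control[["Dam"]][[r]], sim$map)
  })
  r <- replicate_correlation(tr[[1]], tr[[2]])
  expect_gt(r, 0.4)
  expect_lt(r, 0.9)
})
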