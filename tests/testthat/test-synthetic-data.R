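test_that("configuration invariants are enforced", {
  expect_error(sim_config(snv_fraction = 0.8, indel_fraction = 0.1),
               "must equal 1")
  expect_error(sim_config(duplex_probability = 0), "fraction")
  expect_error(sim_config(vaf_levels = c(0.1, 1.5)), "fraction")
  expect_error(sim_config(ss_to_duplex_error_ratio = 0.5), ">= 1")
  cfg <- sim_config()
  expect_equal(haploid_copies(cfg), 20000 / 3.158)
  # 20 ng at 10% VAF carries about 633 alternate input molecules
  expect_equal(round(haploid_copies(cfg) * 0.1), 633)
})

test_that("panel composition follows the configured split", {
  cfg <- sim_config(n_probes = 1800, seed = 5)
  sim <- simulate_panel(cfg)
  expect_equal(sum(sim$panel$variant_class == "SNV"), 1620)
  expect_equal(sum(sim$panel$variant_class == "InDel"), 180)
  expect_true(all(table(sim$panel$substitution_type[
    sim$panel$variant_class == "InDel"]) == 45))
  expect_true(all(sim$panel$indel_length <= 40))
  expect_true(all(sim$truth$lambda_single >= sim$truth$lambda_duplex))

  cfg4 <- sim_config(n_probes = 4, snv_fraction = 0, indel_fraction = 1,
                     seed = 5)
  p4 <- simulate_panel(cfg4)$panel
  expect_setequal(p4$substitution_type, c("SDEL", "SINS", "MDEL", "MINS"))
})

test_that("a fixed seed reproduces panels and counts byte-identically", {
  cfg <- small_config()
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a, b)
  ra <- simulate_counts(a, config = cfg)
  rb <- simulate_counts(b, config = cfg)
  expect_identical(ra$counts, rb$counts)
  expect_identical(ra$controls, rb$controls)
})

test_that("simulated alternate counts match their closed-form means", {
  # fixed probe at the score-200 anchor: overall recovery 0.40 * 0.47,
  # i.e. ~120 of the ~633 alternate input molecules at 10% VAF
  cfg <- small_config(n_probes = 50, score_mean = 200, score_sd = 0,
                      recovery_jitter_sd = 0, sample_sd = 0,
                      vaf_levels = 0.1, replicates_per_level = 200,
                      seed = 11)
  sim <- simulate_panel(cfg)
  run <- simulate_counts(sim, config = cfg)
  C <- haploid_copies(cfg)
  expected <- sim$truth$epsilon * C * 0.1 +
    sim$truth$lambda_duplex + sim$truth$lambda_single
  expect_equal(unique(round(sim$truth$epsilon * C * 0.1)), 119,
               tolerance = 0.02)
  per_probe_mean <- tapply(run$counts$total_alt, run$counts$probe_id, mean)
  per_probe_mean <- per_probe_mean[sim$truth$probe_id]
  # per-probe empirical means within a family-wise 4.5-SE band, and the
  # panel-averaged z within 3 SE of zero
  se <- sqrt(expected / 200)
  z <- (per_probe_mean - expected) / se
  expect_true(all(abs(z) < 4.5))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  # and the grand mean lands on ~120 recovered alternate molecules
  expect_equal(mean(per_probe_mean), mean(expected), tolerance = 0.01)
})

test_that("blanks with zero background and no contamination are silent", {
  cfg <- small_config(vaf_levels = 0, replicates_per_level = 5,
                      error_prior_by_type = zero_priors())
  run <- simulate_counts(simulate_panel(cfg), config = cfg)
  expect_true(all(run$counts$total_alt == 0))
  expect_gt(sum(run$counts$total_wt), 0)
})

test_that("non-selective truth yields global selectivity near 1", {
  cfg <- small_config(n_probes = 60, vaf_levels = c(0.1, 0.01),
                      replicates_per_level = 4,
                      error_prior_by_type = zero_priors(), seed = 9)
  sim <- simulate_panel(cfg)
  sim$truth$selectivity <- rep(1, nrow(sim$truth))
  run <- simulate_counts(sim, config = cfg)
  g <- global_selectivity(run$counts, run$samples)
  # aggregate counts are ~5e5 per sample, so S_g should sit within a few
  # standard errors of 1
  expect_equal(g$S_g, 1, tolerance = 0.02)
})

test_that("read expansion builds bundles with shared breakpoints and UMIs", {
  counts <- data.frame(probe_id = "p1", sample_id = "s1", duplex_alt = 1L,
                       single_strand_alt = 0L, duplex_wt = 0L,
                       single_strand_wt = 0L, total_alt = 1L, total_wt = 0L)
  panel <- data.frame(probe_id = "p1", chrom = "chr7", pos = 5000L)
  cfg <- small_config(reads_per_strand = 2)
  reads <- simulate_reads(counts, panel, cfg)
  expect_equal(nrow(reads), 4L)
  expect_equal(length(unique(reads$umi)), 1L)
  expect_equal(length(unique(paste(reads$start, reads$end))), 1L)
  expect_setequal(unique(reads$strand), c("top", "bottom"))
  expect_true(all(reads$base_at_target == "alt"))
})

test_that("molecule counts round-trip exactly through reads and counting", {
  cfg <- small_config(n_probes = 8, vaf_levels = 0.01,
                      replicates_per_level = 1, umi_error_rate = 0, seed = 3)
  sim <- simulate_panel(cfg)
  run <- simulate_counts(sim, config = cfg)
  reads <- simulate_reads(run, sim$panel, cfg)
  got <- count_molecules(group_read_bundles(reads))
  want <- run$counts[run$counts$probe_id %in% got$probe_id, ]
  merged <- merge(got, want, by = c("probe_id", "sample_id"))
  for (col in c("duplex_alt", "single_strand_alt", "duplex_wt",
                "single_strand_wt")) {
    expect_equal(merged[[paste0(col, ".x")]], merged[[paste0(col, ".y")]])
  }
})

test_that("UMI read errors within the collapse distance do not split bundles", {
  # 100 molecules across probes; each read's UMI may carry up to 2 edits
  cfg <- small_config(n_probes = 20, vaf_levels = 0.001,
                      replicates_per_level = 1, umi_error_rate = 0.3,
                      umi_error_max_edits = 2, breakpoint_jitter = 60,
                      seed = 17)
  sim <- simulate_panel(cfg)
  counts <- data.frame(probe_id = sim$panel$probe_id, sample_id = "s1",
                       duplex_alt = 5L, single_strand_alt = 0L,
                       duplex_wt = 0L, single_strand_wt = 0L,
                       total_alt = 5L, total_wt = 0L)
  reads <- simulate_reads(counts, sim$panel, cfg)
  got <- count_molecules(group_read_bundles(reads, max_edit_distance = 2))
  expect_equal(sum(got$total_alt), 100L)
  expect_equal(unname(table(got$duplex_alt)[["5"]]), 20L)
})

test_that("contaminated blanks carry phased-SNP molecules and dropouts fail QC", {
  cfg <- small_config(n_probes = 30, vaf_levels = c(0.01, 0),
                      replicates_per_level = 3, dropout_probability = 0.5,
                      contamination = list(fraction = 0.002, phased = TRUE,
                                           n_blanks = 2),
                      seed = 23)
  run <- simulate_counts(simulate_panel(cfg), config = cfg)
  expect_equal(sum(run$samples$contaminated), 2L)
  con <- run$contamination
  contaminated <- run$samples$sample_id[run$samples$contaminated]
  expect_true(all(con$n_both_snps[con$sample_id %in% contaminated] > 0))
  expect_true(all(con$n_both_snps <= con$n_covering))
  ctrl_min <- tapply(run$controls$count, run$controls$sample_id, min)
  dropouts <- run$samples$sample_id[run$samples$dropout]
  expect_true(length(dropouts) > 0)
  expect_true(all(ctrl_min[dropouts] < 100))
  expect_true(all(ctrl_min[setdiff(names(ctrl_min), dropouts)] >= 100))
})
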