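make_target <- function(seed = 1, ctx_gc = 0.5, snp_offsets = integer(0)) {
  set.seed(seed)
  ctx <- paste(sample(c("A", "C", "G", "T"), 301, replace = TRUE,
                      prob = c((1 - ctx_gc) / 2, ctx_gc / 2, ctx_gc / 2,
                               (1 - ctx_gc) / 2)), collapse = "")
  variant_target("chr1", 1000L, substr(ctx, 151, 151),
                 setdiff(c("A", "C", "G", "T"), substr(ctx, 151, 151))[1],
                 context = ctx, context_offset = 151L,
                 snp_offsets = snp_offsets)
}

test_that("candidate enumeration is the Cartesian product of flank ranges", {
  tg <- make_target()
  cand <- enumerate_candidates(tg, upstream = 3:10, downstream = 20:30)
  expect_equal(nrow(cand), 8 * 11)
  expect_equal(nrow(enumerate_candidates(tg, upstream = 5, downstream = 20)),
               1)
  both <- enumerate_candidates(tg, upstream = 3:10, downstream = 20:30,
                               both_strands = TRUE)
  expect_equal(nrow(both), 2 * 88)
  expect_error(enumerate_candidates(tg, upstream = 200:210,
                                    downstream = 3:10), "context too short")
  # every candidate contains the variant base at the expected offset
  i <- sample(nrow(cand), 5)
  expect_true(all(substr(cand$sequence[i],
                         cand$upstream[i] + 1, cand$upstream[i] + 1) ==
                    tg$ref))
})

test_that("melting temperature matches an independent reference calculator", {
  # frozen values from a published nearest-neighbour implementation
  # (unified parameters, 50 mM Na+, 250 nM single strand)
  expect_equal(melting_temperature("ACGTGCTAGCTAGGCTACGATCGATCGGTA"),
               66.316, tolerance = 0.5 / 66)
  expect_equal(melting_temperature("ATGCATGCATGCATGCATGCATGC"),
               63.9884, tolerance = 0.5 / 64)
  expect_equal(melting_temperature("GGGCCCGGGCCCGGGCCCGGGCC"),
               81.6555, tolerance = 0.5 / 82)
  # GC-rich extension raises Tm; reverse complement leaves it unchanged
  s <- "ACGTGCTAGCTAGGCTACGATCGATCGGTA"
  expect_gt(melting_temperature(paste0(s, "GCGCGC")),
            melting_temperature(s))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
  expect_equal(melting_temperature(s), melting_temperature(rc))
  expect_error(melting_temperature("ACGTNACGT"), "ambiguity")
  expect_error(melting_temperature("ACGT"), "at least 8")
})

test_that("feature computation covers GC, 3'-geometry, SNP and repeat flags", {
  tg <- make_target()
  f <- compute_features(enumerate_candidates(tg, upstream = 30,
                                             downstream = 7), tg)
  expect_equal(f$gc_content,
               duplexmrd:::gc_content(f$sequence))
  expect_equal(duplexmrd:::gc_content("ATGC"), 0.5)
  expect_equal(f$variant_offset_3prime, 7)
  expect_false(f$snp_within_25bp_3prime)
  # SNP 10 bases upstream of the variant sits inside the probe and within
  # 25 bp of its 3' end
  tg_snp <- make_target(snp_offsets = -10L)
  f2 <- compute_features(enumerate_candidates(tg_snp, upstream = 30,
                                              downstream = 7), tg_snp)
  expect_true(f2$snp_within_25bp_3prime)
  # a SNP outside the probe span does not flag
  f3 <- compute_features(enumerate_candidates(tg_snp, upstream = 5,
                                              downstream = 7), tg_snp)
  expect_false(f3$snp_within_25bp_3prime)
  # homopolymer and tandem repeats near the variant
  expect_true(duplexmrd:::has_repeat_context(
    paste0(strrep("ACGT", 5), "AAAAAA", strrep("TGCA", 5)), 23))
  expect_true(duplexmrd:::has_repeat_context(
    paste0(strrep("GATC", 5), "CACACA", strrep("TGCA", 5)), 23))
  expect_false(duplexmrd:::has_repeat_context(
    "GATCCGTAGCTAGGATCCGATCGTAGCATG", 15))
})

scorer_cache <- new.env()
get_scorer <- function() {
  if (is.null(scorer_cache$s)) {
    scorer_cache$s <- train_probe_scorer(seed = 8)
  }
  scorer_cache$s
}

test_that("the bundled scorer generalises and respects known feature effects", {
  sc <- get_scorer()
  expect_gte(sc$r_squared, 0.6)
  tg <- make_target()
  f <- compute_features(enumerate_candidates(tg, upstream = c(30, 30),
                                             downstream = c(7, 7)), tg)
  scored <- score_probes(f, sc)
  expect_equal(scored$score[1], scored$score[2])  # identical designs
  # raising GC from 0.30 to 0.50 (everything else fixed) does not hurt
  base <- f[1, ]
  lo <- base; lo$gc_content <- 0.30; lo$low_gc <- TRUE
  hi <- base; hi$gc_content <- 0.50; hi$low_gc <- FALSE
  expect_gte(score_probes(hi, sc)$score, score_probes(lo, sc)$score)
})

test_that("best-design selection filters on Tm and breaks ties as documented", {
  d <- data.frame(sequence = c("AAA", "BBB", "CCC"), tm = c(70, 70, 70),
                  score = c(10, 30, 20), length = c(3, 3, 3),
                  stringsAsFactors = FALSE)
  expect_equal(select_best(d)$score, 30)
  d$score <- c(30, 30, 20)
  d$length <- c(5, 3, 3)
  expect_equal(select_best(d)$sequence, "BBB")
  d$length <- c(3, 3, 3)
  expect_equal(select_best(d)$sequence, "AAA")  # lexicographic tie-break
  d$tm <- c(60, 61, 62)
  expect_error(select_best(d), "62")
})

test_that("panel sampling honours composition, thresholds and length caps", {
  set.seed(4)
  n <- 6000
  pool <- data.frame(
    variant_class = sample(c("SNV", "InDel"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
    score = runif(n, 0, 400), stringsAsFactors = FALSE)
  pool$substitution_type <- ifelse(
    pool$variant_class == "SNV",
    sample(c("C>T", "C>A", "T>C"), n, replace = TRUE),
    sample(c("SDEL", "SINS", "MDEL", "MINS"), n, replace = TRUE))
  pool$indel_length <- ifelse(pool$variant_class == "InDel",
                              sample(1:60, n, replace = TRUE), 0L)
  panel <- sample_panel(pool, 1800, snv_fraction = 0.9, seed = 2)
  expect_equal(sum(panel$variant_class == "SNV"), 1620)
  expect_equal(sum(panel$variant_class == "InDel"), 180)
  expect_true(all(table(panel$substitution_type[
    panel$variant_class == "InDel"]) == 45))
  expect_true(all(panel$indel_length <= 40))
  # pool-2 mode: per-type score thresholds on the active scale
  p2 <- sample_panel(pool, 400, pool2_mode = TRUE, snv_threshold = 210,
                     indel_threshold = 85, seed = 2)
  expect_true(all(p2$score[p2$variant_class == "SNV"] > 210))
  expect_true(all(p2$score[p2$variant_class == "InDel"] > 85))
  # reproducible under a fixed seed
  expect_identical(sample_panel(pool, 400, seed = 9),
                   sample_panel(pool, 400, seed = 9))
  expect_error(sample_panel(pool[pool$variant_class == "InDel", ], 100,
                            snv_fraction = 0.9), "SNV")
})

test_that("recovered molecules correlate with the design score at 10% VAF", {
  cfg <- small_config(n_probes = 300, vaf_levels = 0.1,
                      replicates_per_level = 4, seed = 61)
  sim <- simulate_panel(cfg)
  run <- simulate_counts(sim, config = cfg)
  mean_alt <- tapply(run$counts$total_alt, run$counts$probe_id, mean)
  r <- cor(sim$panel$score, as.numeric(mean_alt[sim$panel$probe_id]))
  expect_gte(r, 0.7)
})
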