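test_that("sample scaling is the geometric mean of control ratios", {
  expect_equal(sample_scaling(c(400, 400), c(400, 400)), 1)
  expect_equal(sample_scaling(c(800, 800), c(400, 400)), 2)
  expect_equal(sample_scaling(c(200, 800), c(400, 400)), 1)  # sqrt(0.5 * 2)
  expect_equal(sample_scaling(c(400, 400), c(400, 400), lib_mass = 30,
                              reference_lib_mass = 20), 1.5)
  expect_true(is.na(sample_scaling(c(0, 0), c(400, 400))))
})

test_that("the score link drives per-probe signal rates with exclusions", {
  expect_equal(probe_signal_rate(c(200, 200)),
               rep(score_to_recovery(200), 2))
  # anchor: score 200 -> 47% enrichment-step efficiency on a 40% library
  expect_equal(score_to_recovery(200), 0.40 * 0.47, tolerance = 1e-9)
  expect_equal(probe_signal_rate(30), 0)   # below the non-functional floor
  expect_equal(probe_signal_rate(250, ms_flag = TRUE), 0)
  expect_equal(probe_signal_rate(250, snp_flag = TRUE), 0)
  expect_gt(probe_signal_rate(300), probe_signal_rate(100))
})

make_spec <- function(n = 1, rho = 0.19, alpha = 0.1, beta = 100,
                      copies = 1000, duplex_prob = 0.5, ...) {
  bg <- data.frame(probe_id = paste0("p", seq_len(n)),
                   alpha_duplex = alpha, beta_duplex = beta,
                   alpha_single = alpha, beta_single = beta)
  mrd_model_spec(stats::setNames(rep(rho, n), bg$probe_id), bg,
                 copies = copies, duplex_prob = duplex_prob, ...)
}

test_that("a silent sample with tight background is not called", {
  spec <- make_spec(n = 5, beta = 1000)
  counts <- data.frame(probe_id = paste0("p", 1:5), duplex_alt = 0L,
                       single_strand_alt = 0L)
  res <- mrd_posterior(counts, spec)
  expect_lt(res$probability_mrd, 0.5)
  expect_false(call_mrd(res, 0.99))
})

test_that("the posterior matches a brute-force evaluation of the likelihood", {
  # single probe, background mean 0.001, rho*G*C = 1000, 10 duplex molecules
  spec <- make_spec(n = 1, rho = 1, copies = 1000, alpha = 0.01, beta = 10,
                    duplex_prob = 1)
  counts <- data.frame(probe_id = "p1", duplex_alt = 10L,
                       single_strand_alt = 0L)
  res <- mrd_posterior(counts, spec)
  expect_gt(res$probability_mrd, 0.99)
  expect_lt(abs(log(res$level_estimate / 0.01)), log(1.5))

  # independent brute-force evaluation over the same grid
  theta <- c(0, spec$theta_grid)
  ll <- vapply(theta, function(t) {
    s <- t * 1000
    p <- 10 / 11
    j <- 0:10
    log(sum(dpois(j, s) * dnbinom(10 - j, size = 0.01, prob = p)))
  }, numeric(1))
  prior <- c(log(0.5), rep(log(0.5 / length(spec$theta_grid)),
                           length(spec$theta_grid)))
  w <- exp(ll + prior - max(ll + prior))
  w <- w / sum(w)
  expect_equal(res$probability_mrd, 1 - w[1], tolerance = 1e-10)
  cdf <- cumsum(w[-1]) / sum(w[-1])
  expect_equal(res$level_estimate, spec$theta_grid[which(cdf >= 0.5)[1]])
})

test_that("rho and theta are only identified through their product", {
  counts <- data.frame(probe_id = paste0("p", 1:3), duplex_alt = c(2L, 0L, 1L),
                       single_strand_alt = c(1L, 0L, 0L))
  a <- mrd_posterior(counts, make_spec(n = 3, rho = 0.2, copies = 5000))
  b <- mrd_posterior(counts, make_spec(n = 3, rho = 0.4, copies = 5000))
  # doubling rho shifts the level estimate down by ~2x at equal evidence
  expect_equal(a$probability_mrd, b$probability_mrd, tolerance = 0.05)
  expect_equal(a$level_estimate / b$level_estimate, 2, tolerance = 0.1)
})

test_that("the posterior is invariant to probe order", {
  set.seed(3)
  n <- 20
  counts <- data.frame(probe_id = paste0("p", 1:n),
                       duplex_alt = rpois(n, 0.5),
                       single_strand_alt = rpois(n, 0.5))
  spec <- make_spec(n = n)
  a <- mrd_posterior(counts, spec)
  b <- mrd_posterior(counts[sample(n), ], spec)
  expect_equal(a$probability_mrd, b$probability_mrd, tolerance = 1e-12)
  expect_equal(a$level_estimate, b$level_estimate)
})

test_that("MRD calls are monotone in the posterior threshold", {
  spec <- make_spec(n = 2)
  counts <- data.frame(probe_id = c("p1", "p2"), duplex_alt = c(3L, 2L),
                       single_strand_alt = c(1L, 1L))
  res <- mrd_posterior(counts, spec)
  calls <- vapply(c(0.5, 0.9, 0.99, 0.999, 1 - 1e-9), function(t) {
    call_mrd(res, t)
  }, logical(1))
  expect_true(all(diff(as.integer(calls)) <= 0))
  expect_true(call_mrd(list(probability_mrd = 0.999, qc_status = "pass"),
                       0.99))
  expect_false(call_mrd(list(probability_mrd = 0.5, qc_status = "pass"),
                        0.99))
})

test_that("failed-QC samples carry their status and are never called", {
  spec <- make_spec(n = 1)
  counts <- data.frame(probe_id = "p1", duplex_alt = 50L,
                       single_strand_alt = 50L)
  res <- mrd_posterior(counts, spec, qc_status = "failed")
  expect_equal(res$qc_status, "failed")
  expect_false(call_mrd(res))
})

test_that("cohort-level calling recovers a small dilution series", {
  cfg <- small_config(n_probes = 150, vaf_levels = c(0.01, 1e-3, 0),
                      replicates_per_level = 3, snv_fraction = 1,
                      indel_fraction = 0, seed = 47)
  sim <- simulate_panel(cfg)
  run <- simulate_counts(sim, config = cfg)
  blanks <- run$samples$sample_id[run$samples$vaf == 0]
  bg <- fit_background_model(run$counts[run$counts$sample_id %in% blanks, ],
                             sim$panel)
  mrd <- mrd_call_cohort(run, sim$panel, bg$site, cfg,
                         stats::setNames(sim$controls$reference_count,
                                         sim$controls$control_id))
  truth <- run$samples$vaf[match(mrd$sample_id, run$samples$sample_id)]
  expect_true(all(mrd$called[truth >= 1e-3]))
  pos <- truth > 0
  expect_equal(log10(mrd$level_estimate[pos]), log10(truth[pos]),
               tolerance = 0.15)
})
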