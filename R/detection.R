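# Per-variant detection machinery: false-positive budget, calling thresholds
# under the Gamma-marginalised Poisson background, probe-performance
# calibration, LoD95 estimation and posterior input-VAF inference.

#' Per-variant false-positive rate budget
#'
#' The FPR per variant that keeps the expected number of false-positive
#' variant calls below one across a cohort:
#' `1 / (n_samples * n_variants)`.
#'
#' @param n_samples cohort size (default 160).
#' @param n_variants variants tracked per sample.
#' @export
#' @examples
#' fpr_budget(160, 2199)  # ~2.84e-6
fpr_budget <- function(n_samples = 160, n_variants) {
  assert_count(n_samples, "n_samples", min = 1L)
  assert_count(n_variants, "n_variants", min = 1L)
  1 / (n_samples * n_variants)
}

#' Minimal calling threshold meeting an FPR bound
#'
#' Smallest count `k*` whose upper-tail probability under the background
#' model is at most `fpr`. With a Gamma prior on the background rate the
#' marginal count distribution is negative binomial
#' (`size = alpha`, `prob = beta / (beta + 1)`); with a fixed rate `lambda`
#' the tail is Poisson. A degenerate zero background yields `k* = 1`: any
#' signal exceeds it.
#'
#' @param prior a `background_prior` (or NULL when `lambda` is given).
#' @param fpr per-variant false-positive bound in (0, 1).
#' @param lambda optional fixed background rate instead of a prior.
#' @return integer threshold `k*`.
#' @export
call_threshold <- function(prior = NULL, fpr, lambda = NULL) {
  if (!is.finite(fpr) || fpr <= 0 || fpr >= 1) {
    stop("fpr must lie in (0, 1)", call. = FALSE)
  }
  stopifnot(!is.null(prior) || !is.null(lambda))
  k <- 1L
  repeat {
    tail <- if (!is.null(lambda)) {
      background_tail(k, lambda = lambda)
    } else {
      background_tail(k, alpha = prior$alpha, beta = prior$beta)
    }
    if (tail <= fpr) return(k)
    k <- k + 1L
    if (k > 1e6) stop("threshold search did not converge", call. = FALSE)
  }
}

#' Calibrate a probe's performance from known-VAF samples
#'
#' Maximum-likelihood Poisson rate of recovered alternate molecules per unit
#' exposure (`scaling * copies * vaf`), after subtracting the prior-mean
#' background, floored at zero:
#' `r_hat = max(0, (sum(x) - N * bg_mean) / sum(s_i * C * f_i))`.
#'
#' @param x alternate molecule counts in the calibration samples.
#' @param scaling per-sample scaling factors `s_i`.
#' @param copies haploid genome copies `C`.
#' @param vaf known input VAF(s) of the calibration samples.
#' @param prior optional `background_prior`; its mean is subtracted.
#' @param posterior when TRUE, also return the Gamma posterior of the rate
#'   (`shape = sum(x) - bg` floored at 0.5, `rate = exposure`), used to
#'   propagate calibration uncertainty into [infer_vaf()].
#' @return estimated rate `r_hat` (expected recovered alternate molecules per
#'   unit copies x VAF), or with `posterior = TRUE` a list
#'   `(rate, shape, rate_param)`.
#' @export
#' @examples
#' calibrate_probe_performance(120, 1, 6333, 0.10)  # ~0.19
calibrate_probe_performance <- function(x, scaling, copies, vaf,
                                        prior = NULL, posterior = FALSE) {
  stopifnot(length(x) >= 1L)
  exposure <- sum(scaling * copies * vaf)
  if (exposure <= 0) return(NA_real_)
  bg <- if (is.null(prior)) 0 else length(x) * prior$alpha / prior$beta
  r_hat <- max(0, (sum(x) - bg) / exposure)
  if (!posterior) return(r_hat)
  list(rate = r_hat, shape = max(sum(x) - bg, 0.5), rate_param = exposure)
}

#' LoD95: input VAF at which 95% of samples are called
#'
#' Solves, by bisection on the mean scale at a fixed (median) sample scaling,
#' for the smallest VAF `f` at which
#' `P(X >= k* | X ~ Poisson(r * s * C * f + bg_mean)) >= power`,
#' with `k*` the calling threshold meeting `fpr` under the background prior.
#'
#' @param rate calibrated probe performance `r` (alternate molecules per unit
#'   copies x VAF).
#' @param prior `background_prior` for the probe (or NULL with
#'   `lambda` fixed).
#' @param fpr per-variant false-positive bound.
#' @param copies haploid genome copies.
#' @param scaling sample scaling at which to evaluate (default 1, the
#'   median sample).
#' @param power required detection probability (default 0.95).
#' @param lambda optional fixed background rate.
#' @param tol absolute bisection tolerance on `f` (default 1e-6).
#' @return list with `lod95` (VAF, capped at 1; `Inf` when `rate = 0`,
#'   i.e. reported as "> 100%") and `k_star`.
#' @export
lod95 <- function(rate, prior = NULL, fpr, copies, scaling = 1,
                  power = 0.95, lambda = NULL, tol = 1e-6) {
  k_star <- call_threshold(prior, fpr, lambda = lambda)
  bg_mean <- if (!is.null(lambda)) lambda else prior$alpha / prior$beta
  if (rate <= 0) return(list(lod95 = Inf, k_star = k_star))
  detect_prob <- function(f) {
    stats::ppois(k_star - 1, rate * scaling * copies * f + bg_mean,
                 lower.tail = FALSE)
  }
  if (detect_prob(1) < power) return(list(lod95 = 1, k_star = k_star))
  lo <- 0
  hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (detect_prob(mid) >= power) hi <- mid else lo <- mid
  }
  list(lod95 = hi, k_star = k_star)
}

#' Posterior input VAF from duplex and single-strand counts
#'
#' Grid posterior over the input VAF `f` (log-spaced grid, default
#' `1e-7 .. 1`, 500 points) under independent Poisson likelihoods for the
#' duplex and single-strand channels. Channel signal means are
#' `r * d * s * C * f` and `r * (1 - d) * s * C * f` (shared `f`,
#' channel-specific rates), and each channel's Gamma background prior is
#' marginalised exactly (Poisson-negative binomial convolution).
#'
#' @param duplex_count,single_count observed alternate molecule counts.
#' @param rate calibrated probe performance: either a plug-in scalar `r` or
#'   the posterior list from `calibrate_probe_performance(..., posterior =
#'   TRUE)`, in which case the rate's Gamma posterior is marginalised
#'   (propagating calibration uncertainty into the interval).
#' @param duplex_prob expected duplex fraction `d` of recovered molecules.
#' @param prior_duplex,prior_single `background_prior`s per channel (NULL for
#'   no background).
#' @param copies,scaling exposure terms.
#' @param grid optional VAF grid; defaults to
#'   `exp(seq(log(1e-7), log(1), length.out = n_grid))`.
#' @param n_grid grid resolution (default 500).
#' @param level credible level (default 0.95).
#' @return list with `mean`, `lower`, `upper` (central credible interval),
#'   and the `grid`/`posterior` vectors.
#' @export
infer_vaf <- function(duplex_count, single_count, rate, duplex_prob = 0.5,
                      prior_duplex = NULL, prior_single = NULL,
                      copies, scaling = 1, grid = NULL, n_grid = 500,
                      level = 0.95) {
  if (is.null(grid)) {
    grid <- exp(seq(log(1e-7), log(1), length.out = n_grid))
  }
  k_dup <- duplex_prob * scaling * copies * grid
  k_ss <- (1 - duplex_prob) * scaling * copies * grid
  if (is.list(rate)) {
    ll <- dnbinom_gamma_bg(duplex_count, k_dup, rate$shape, rate$rate_param,
                           prior_duplex$alpha %||% 0,
                           prior_duplex$beta %||% 1) +
      dnbinom_gamma_bg(single_count, k_ss, rate$shape, rate$rate_param,
                       prior_single$alpha %||% 0, prior_single$beta %||% 1)
  } else {
    ll <- dpois_gamma_bg(duplex_count, rate * k_dup,
                         prior_duplex$alpha %||% 0,
                         prior_duplex$beta %||% 1) +
      dpois_gamma_bg(single_count, rate * k_ss,
                     prior_single$alpha %||% 0, prior_single$beta %||% 1)
  }
  lp <- ll - log_sum_exp(ll)
  post <- exp(lp)
  cdf <- cumsum(post)
  a <- (1 - level) / 2
  # credible bounds rounded outward on the discrete grid
  list(mean = sum(grid * post),
       lower = grid[max(1L, which(cdf >= a)[1L] - 1L)],
       upper = grid[which(cdf >= 1 - a)[1L]],
       grid = grid, posterior = post)
}

#' Per-probe LoD95 table for a cohort
#'
#' Calibrates each probe's performance on the highest-VAF samples and solves
#' its LoD95 at the given FPR under the probe's site-specific background
#' prior (duplex and single-strand channels pooled).
#'
#' @param counts molecule-count table (QC-passing samples).
#' @param samples sample table with `sample_id, vaf, scaling`.
#' @param bg_site site-specific background table
#'   (`fit_background_model()$site`).
#' @param copies haploid genome copies.
#' @param fpr per-variant false-positive bound.
#' @param calibration_vaf VAF level used for calibration (default: the
#'   highest level present).
#' @return data frame `probe_id, rate, k_star, lod95`.
#' @export
lod_table <- function(counts, samples, bg_site, copies, fpr,
                      calibration_vaf = max(samples$vaf)) {
  calib_ids <- samples$sample_id[samples$vaf == calibration_vaf]
  calib <- samples[match(calib_ids, samples$sample_id), ]
  rows <- lapply(unique(counts$probe_id), function(pid) {
    cc <- counts[counts$probe_id == pid &
                   counts$sample_id %in% calib_ids, ]
    site <- bg_site[bg_site$probe_id == pid, ]
    prior <- new_background_prior(site$alpha_duplex + site$alpha_single,
                                  site$beta_duplex, "site-specific")
    r <- calibrate_probe_performance(cc$total_alt, calib$scaling, copies,
                                     calib$vaf, prior)
    l <- lod95(r, prior, fpr, copies)
    data.frame(probe_id = pid, rate = r, k_star = l$k_star, lod95 = l$lod95,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior input VAF for every probe x sample of a cohort
#'
#' Calibrates per-probe rates (with their Gamma posteriors) on the
#' calibration-VAF samples and infers the input VAF of every other sample.
#'
#' @inheritParams lod_table
#' @param duplex_prob expected duplex fraction.
#' @return data frame `probe_id, sample_id, vaf_mean, vaf_lower, vaf_upper`.
#' @export
infer_vaf_cohort <- function(counts, samples, bg_site, copies,
                             duplex_prob = 0.5,
                             calibration_vaf = max(samples$vaf)) {
  calib_ids <- samples$sample_id[samples$vaf == calibration_vaf]
  eval_ids <- setdiff(samples$sample_id, calib_ids)
  calib <- samples[match(calib_ids, samples$sample_id), ]
  rows <- list()
  for (pid in unique(counts$probe_id)) {
    cc <- counts[counts$probe_id == pid, ]
    site <- bg_site[bg_site$probe_id == pid, ]
    pr_d <- new_background_prior(site$alpha_duplex, site$beta_duplex,
                                 "site-specific")
    pr_s <- new_background_prior(site$alpha_single, site$beta_single,
                                 "site-specific")
    cal <- cc[cc$sample_id %in% calib_ids, ]
    r <- calibrate_probe_performance(
      cal$total_alt, calib$scaling, copies, calib$vaf, posterior = TRUE,
      prior = new_background_prior(site$alpha_duplex + site$alpha_single,
                                   site$beta_duplex, "site-specific"))
    for (sid in eval_ids) {
      row <- cc[cc$sample_id == sid, ]
      if (!nrow(row)) next
      p <- infer_vaf(row$duplex_alt, row$single_strand_alt, r, duplex_prob,
                     prior_duplex = pr_d, prior_single = pr_s,
                     copies = copies,
                     scaling = samples$scaling[samples$sample_id == sid])
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = pid, sample_id = sid, vaf_mean = p$mean,
        vaf_lower = p$lower, vaf_upper = p$upper, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Nested cross-validated VAF predictions
#'
#' Outer folds hold out samples; on each training split the probe performance
#' is re-calibrated and an inner leave-one-out loop over the training samples
#' selects the posterior grid resolution by held-out prediction error.
#' Held-out samples are then predicted with the selected settings only.
#'
#' @param counts molecule-count table (`probe_id, sample_id, duplex_alt,
#'   single_strand_alt`).
#' @param samples sample table with `sample_id, vaf, scaling`.
#' @param copies haploid genome copies.
#' @param duplex_prob duplex fraction.
#' @param folds number of outer folds (<= number of samples).
#' @param grid_candidates inner-loop candidates for the grid resolution.
#' @param seed fold-assignment seed.
#' @return data frame `probe_id, sample_id, vaf_true, vaf_pred, fold`.
#' @export
crossvalidate_vaf <- function(counts, samples, copies, duplex_prob = 0.5,
                              folds = nrow(samples),
                              grid_candidates = c(200, 500), seed = 1L) {
  n <- nrow(samples)
  if (folds > n) stop("folds must not exceed the number of samples",
                      call. = FALSE)
  if (n < 2L) stop("need >= 2 calibration samples", call. = FALSE)
  set.seed(substream_seed(seed, "folds"))
  fold_of <- sample(rep(seq_len(folds), length.out = n))

  predict_samples <- function(train_ids, test_ids, n_grid) {
    out <- list()
    for (pid in unique(counts$probe_id)) {
      cc <- counts[counts$probe_id == pid, ]
      tr <- cc[cc$sample_id %in% train_ids, ]
      trs <- samples[match(tr$sample_id, samples$sample_id), ]
      r <- calibrate_probe_performance(
        tr$duplex_alt + tr$single_strand_alt, trs$scaling, copies, trs$vaf)
      for (sid in test_ids) {
        row <- cc[cc$sample_id == sid, ]
        if (!nrow(row)) next
        sc <- samples$scaling[samples$sample_id == sid]
        p <- infer_vaf(row$duplex_alt, row$single_strand_alt, r,
                       duplex_prob, copies = copies, scaling = sc,
                       n_grid = n_grid)
        out[[length(out) + 1L]] <- data.frame(
          probe_id = pid, sample_id = sid,
          vaf_true = samples$vaf[samples$sample_id == sid],
          vaf_pred = p$mean, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }

  res <- list()
  for (k in seq_len(folds)) {
    test_ids <- samples$sample_id[fold_of == k]
    train_ids <- setdiff(samples$sample_id, test_ids)
    # inner leave-one-out over the training samples to pick the grid size
    best <- grid_candidates[1L]
    if (length(grid_candidates) > 1L && length(train_ids) >= 2L) {
      errs <- vapply(grid_candidates, function(g) {
        e <- 0
        for (held in train_ids) {
          pr <- predict_samples(setdiff(train_ids, held), held, g)
          if (!is.null(pr)) {
            e <- e + mean((log10(pmax(pr$vaf_pred, 1e-7)) -
                             log10(pmax(pr$vaf_true, 1e-7)))^2)
          }
        }
        e
      }, numeric(1))
      best <- grid_candidates[which.min(errs)]
    }
    pr <- predict_samples(train_ids, test_ids, best)
    if (!is.null(pr)) {
      pr$fold <- k
      res[[length(res) + 1L]] <- pr
    }
  }
  do.call(rbind, res)
}
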