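# Sample-level MRD detection and quantification: duplex and non-duplex
# alternate counts for all usable SNV probes are integrated under a
# background + signal Bayesian model into P(MRD) and an MRD-level estimate.

#' Sample scaling factor from control probes and input masses
#'
#' Geometric mean of the per-control count ratios against a reference panel,
#' multiplied by the library and capture input-mass ratios. Captures
#' sample-to-sample variability of the assay's overall molecule yield.
#'
#' @param control_counts observed counts for the sample's control probes.
#' @param reference_counts matching reference counts (same order).
#' @param lib_mass,reference_lib_mass input mass into library preparation.
#' @param capture_mass,reference_capture_mass input mass into target capture.
#' @return scaling factor `G_i` (> 0), or `NA` when every control count is 0
#'   (failed sample; see [detect_failed_sample()]).
#' @export
#' @examples
#' sample_scaling(c(200, 800), c(400, 400))  # 1
sample_scaling <- function(control_counts, reference_counts,
                           lib_mass = 1, reference_lib_mass = 1,
                           capture_mass = 1, reference_capture_mass = 1) {
  stopifnot(length(control_counts) == length(reference_counts),
            length(control_counts) >= 1L)
  if (all(control_counts == 0)) return(NA_real_)
  keep <- control_counts > 0 & reference_counts > 0
  geometric_mean(control_counts[keep] / reference_counts[keep]) *
    (lib_mass / reference_lib_mass) *
    (capture_mass / reference_capture_mass)
}

#' Per-probe MRD signal rate from the design score
#'
#' Monotone link from a probe's predicted design score to its expected
#' alternate molecule yield per unit MRD level (at reference sample scale and
#' per haploid copy), via [score_to_recovery()]. Probes flagged as targeting
#' microsatellite contexts or overlapping a SNP, or scoring below the
#' non-functional floor, get rate 0 and are excluded from MRD scoring.
#'
#' @param score design score(s).
#' @param ms_flag,snp_flag exclusion flags (recycled).
#' @param floor_score scores below this are treated as non-functional
#'   (default 60).
#' @param library_efficiency passed to [score_to_recovery()].
#' @return per-probe rate `rho_p` (0 for excluded probes).
#' @export
probe_signal_rate <- function(score, ms_flag = FALSE, snp_flag = FALSE,
                              floor_score = 60, library_efficiency = 0.40) {
  rho <- score_to_recovery(score, library_efficiency)
  rho[ms_flag | snp_flag | score < floor_score] <- 0
  rho
}

#' MRD model specification
#'
#' Packages the ingredients of the MRD posterior: a log-spaced grid of MRD
#' levels theta plus an explicit theta = 0 atom with prior mass `null_mass`,
#' per-probe signal rates, per-probe Gamma background priors for the duplex
#' and single-strand channels, the haploid copy number and the single-strand
#' channel weight (0 disables that channel).
#'
#' @param rho named numeric vector of per-probe signal rates (probes with 0
#'   are excluded).
#' @param bg data frame with `probe_id, alpha_duplex, beta_duplex,
#'   alpha_single, beta_single` (e.g. `fit_background_model()$site`).
#' @param copies haploid genome copies.
#' @param duplex_prob expected duplex fraction of recovered molecules.
#' @param theta_grid grid of positive MRD levels; default 400 log-spaced
#'   points on `[1e-7, 0.2]`.
#' @param null_mass prior mass on theta = 0 (default 0.5; the rest is spread
#'   uniformly over the grid).
#' @param ss_weight weight of the single-strand log-likelihood (default 1).
#' @return list of class `mrd_model_spec`.
#' @export
mrd_model_spec <- function(rho, bg, copies, duplex_prob = 0.5,
                           theta_grid = NULL, null_mass = 0.5,
                           ss_weight = 1) {
  if (is.null(theta_grid)) {
    theta_grid <- exp(seq(log(1e-7), log(0.2), length.out = 400))
  }
  stopifnot(all(diff(theta_grid) > 0), all(theta_grid > 0))
  assert_fraction(null_mass, "null_mass", open_left = TRUE, open_right = TRUE)
  structure(list(rho = rho, bg = bg, copies = copies,
                 duplex_prob = duplex_prob, theta_grid = theta_grid,
                 null_mass = null_mass, ss_weight = ss_weight),
            class = "mrd_model_spec")
}

#' MRD posterior for one sample
#'
#' For each MRD level theta on `{0} U grid`, the log-likelihood sums over all
#' usable probes the exact Gamma-marginalised Poisson log-density of the
#' duplex count (signal mean `theta * rho_p * d * G_i * C` plus the probe's
#' duplex background) and, weighted by `ss_weight`, of the single-strand
#' count (mean `theta * rho_p * (1 - d) * G_i * C` plus the single-strand
#' background). The posterior over theta yields the probability of MRD
#' (posterior mass on theta > 0) and the MRD level (posterior median and
#' central 95% interval of theta given theta > 0).
#'
#' @param counts molecule-count table for one sample (`probe_id, duplex_alt,
#'   single_strand_alt`); InDel / flagged probes should already have rate 0
#'   in the spec (they are skipped).
#' @param spec an [mrd_model_spec()].
#' @param scaling sample scaling factor `G_i` (see [sample_scaling()]).
#' @param qc_status QC label carried into the result; anything other than
#'   `"pass"` suppresses the call.
#' @param level credible level for the MRD-level interval.
#' @return list of class `mrd_result`: `probability_mrd`, `level_estimate`,
#'   `lower`, `upper`, `n_probes_used`, `qc_status`, plus the
#'   `total_duplex_alt` blank-diagnostic tally.
#' @export
mrd_posterior <- function(counts, spec, scaling = 1, qc_status = "pass",
                          level = 0.95) {
  stopifnot(inherits(spec, "mrd_model_spec"))
  if (!identical(qc_status, "pass")) {
    return(structure(list(probability_mrd = NA_real_,
                          level_estimate = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          called = FALSE, n_probes_used = 0L,
                          qc_status = qc_status,
                          total_duplex_alt = NA_integer_),
                     class = "mrd_result"))
  }
  use <- names(spec$rho)[spec$rho > 0]
  use <- intersect(use, counts$probe_id)
  if (!length(use)) stop("no usable probes for MRD scoring", call. = FALSE)

  idx <- match(use, counts$probe_id)
  bg <- spec$bg[match(use, spec$bg$probe_id), ]
  rho <- spec$rho[use]
  theta <- c(0, spec$theta_grid)
  ll <- numeric(length(theta))
  d <- spec$duplex_prob
  for (j in seq_along(use)) {
    unit <- rho[j] * scaling * spec$copies
    ll <- ll + dpois_gamma_bg(counts$duplex_alt[idx[j]], theta * unit * d,
                              bg$alpha_duplex[j], bg$beta_duplex[j])
    if (spec$ss_weight > 0) {
      ll <- ll + spec$ss_weight *
        dpois_gamma_bg(counts$single_strand_alt[idx[j]],
                       theta * unit * (1 - d),
                       bg$alpha_single[j], bg$beta_single[j])
    }
  }
  n_grid <- length(spec$theta_grid)
  log_prior <- c(log(spec$null_mass),
                 rep(log((1 - spec$null_mass) / n_grid), n_grid))
  lp <- ll + log_prior
  lp <- lp - log_sum_exp(lp)
  post <- exp(lp)
  p_mrd <- sum(post[-1L])

  post_pos <- post[-1L] / p_mrd
  cdf <- cumsum(post_pos)
  a <- (1 - level) / 2
  structure(list(
    probability_mrd = p_mrd,
    level_estimate = spec$theta_grid[which(cdf >= 0.5)[1L]],
    lower = spec$theta_grid[max(1L, which(cdf >= a)[1L] - 1L)],
    upper = spec$theta_grid[which(cdf >= 1 - a)[1L]],
    called = NA,
    n_probes_used = length(use),
    qc_status = qc_status,
    total_duplex_alt = sum(counts$duplex_alt[idx])),
    class = "mrd_result")
}

#' @export
print.mrd_result <- function(x, ...) {
  cat(sprintf(
    "MRD result: P(MRD) = %.4f, level = %.3g (95%% CI %.3g-%.3g), %d probes, QC %s\n",
    x$probability_mrd, x$level_estimate, x$lower, x$upper,
    x$n_probes_used, x$qc_status))
  invisible(x)
}

#' Binary MRD call at a posterior threshold
#'
#' @param result an `mrd_result`.
#' @param posterior_threshold call iff `probability_mrd >=` this (default
#'   0.99, set so that simulated blank cohorts produce no false positives).
#' @return logical call (`FALSE` for failed-QC samples).
#' @export
call_mrd <- function(result, posterior_threshold = 0.99) {
  if (!identical(result$qc_status, "pass") || is.na(result$probability_mrd)) {
    return(FALSE)
  }
  result$probability_mrd >= posterior_threshold
}

#' MRD calling across a cohort
#'
#' Applies [sample_scaling()], QC ([detect_failed_sample()]),
#' [mrd_posterior()] and [call_mrd()] to every sample of an assay run.
#' InDel-targeting and MS/SNP-flagged probes are excluded by default via
#' [probe_signal_rate()].
#'
#' @param run an `assay_run` (or list with `counts`, `controls`, `samples`).
#' @param panel panel table.
#' @param bg site-specific background table (`fit_background_model()$site`).
#' @param config the `sim_config` (for copies, duplex probability and the
#'   score link); alternatively pass `copies` explicitly.
#' @param reference_controls reference control counts (named by control_id).
#' @param posterior_threshold call threshold (default 0.99).
#' @param snv_only exclude InDel probes (default TRUE).
#' @param ss_weight single-strand channel weight.
#' @return data frame, one row per sample: probability, level estimate with
#'   interval, call, QC status and the duplex-molecule blank diagnostic.
#' @export
mrd_call_cohort <- function(run, panel, bg, config, reference_controls,
                            posterior_threshold = 0.99, snv_only = TRUE,
                            ss_weight = 1) {
  rho <- probe_signal_rate(panel$score, panel$ms_flag, panel$snp_flag,
                           library_efficiency = config$library_efficiency)
  if (snv_only) rho[panel$variant_class != "SNV"] <- 0
  names(rho) <- panel$probe_id
  spec <- mrd_model_spec(rho, bg, copies = haploid_copies(config),
                         duplex_prob = config$duplex_probability,
                         ss_weight = ss_weight)
  rows <- list()
  for (sid in unique(run$samples$sample_id)) {
    ctrl <- run$controls[run$controls$sample_id == sid, ]
    ref <- reference_controls[ctrl$control_id]
    qc <- detect_failed_sample(stats::setNames(ctrl$count, ctrl$control_id))
    status <- if (qc$failed) "failed" else "pass"
    G <- if (qc$failed) NA_real_ else sample_scaling(ctrl$count, ref)
    cc <- run$counts[run$counts$sample_id == sid, ]
    res <- mrd_posterior(cc, spec, scaling = if (is.na(G)) 1 else G,
                         qc_status = status)
    rows[[sid]] <- data.frame(
      sample_id = sid,
      probability_mrd = res$probability_mrd,
      level_estimate = res$level_estimate,
      lower = res$lower, upper = res$upper,
      called = call_mrd(res, posterior_threshold),
      n_probes_used = res$n_probes_used,
      qc_status = res$qc_status,
      total_duplex_alt = res$total_duplex_alt,
      scaling = G,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
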