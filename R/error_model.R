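# Background error models estimated from blank (expected-negative) samples:
# per-site rate estimates and the two Gamma priors (substitution-type-level
# by moment matching, and site-specific conjugate posteriors).

new_background_prior <- function(alpha, beta, scope,
                                 substitution_type = NA_character_) {
  assert_positive(alpha, "alpha")
  assert_positive(beta, "beta")
  structure(list(alpha = alpha, beta = beta, scope = scope,
                 substitution_type = substitution_type),
            class = "background_prior")
}

#' @export
print.background_prior <- function(x, ...) {
  cat(sprintf("Gamma background prior (%s%s): alpha = %.4g, beta = %.4g, mean = %.4g\n",
              x$scope,
              if (is.na(x$substitution_type)) "" else paste0(", ",
                                                             x$substitution_type),
              x$alpha, x$beta, x$alpha / x$beta))
  invisible(x)
}

#' Per-site background error rate estimate
#'
#' The arithmetic mean of observed error-molecule counts for a probe across
#' blank samples.
#'
#' @param x non-negative integer counts, one per sample.
#' @return rate estimate (`NA` for empty input).
#' @export
per_site_error_rate <- function(x) {
  if (!length(x)) return(NA_real_)
  assert_count(x, "counts")
  mean(x)
}

#' Substitution-type Gamma prior by moment matching
#'
#' Given per-site error-rate estimates for all probes of one substitution
#' type, matches a Gamma distribution by moments: `alpha = mu^2 / sigma^2`,
#' `beta = mu / sigma^2`, where `mu` is the mean of the per-site rates and
#' `sigma^2` their variance (population, i.e. 1/N, convention by default).
#'
#' @param rates per-site rate estimates (length >= 2).
#' @param substitution_type label stored on the prior.
#' @param variance `"population"` (1/N, default) or `"sample"` (1/(N-1)).
#' @return a `background_prior` with scope `"substitution-type"`.
#' @export
type_prior <- function(rates, substitution_type = NA_character_,
                       variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (length(rates) < 2L) {
    stop("need >= 2 probes of the type to moment-match a prior",
         call. = FALSE)
  }
  mu <- mean(rates)
  s2 <- stats::var(rates)
  if (variance == "population") s2 <- s2 * (length(rates) - 1) / length(rates)
  if (!is.finite(s2) || s2 <= 0) {
    stop("zero variance across probes: a type-level prior is degenerate; ",
         "use the site-specific prior instead", call. = FALSE)
  }
  new_background_prior(mu^2 / s2, mu / s2, "substitution-type",
                       substitution_type)
}

#' Site-specific Gamma posterior prior
#'
#' The Gamma posterior for a site's error rate given counts
#' `x_i ~ Poisson(lambda)` under the prior `Gamma(alpha = 0.1, beta = 1)`:
#' `alpha = 0.1 + sum(x)`, `beta = 1 + N`. Used as the per-site prior of the
#' detection and MRD models.
#'
#' @param x observed error-molecule counts across blank samples (N >= 1).
#' @param prior_alpha,prior_beta hyperparameters of the base prior.
#' @return a `background_prior` with scope `"site-specific"`.
#' @export
site_prior <- function(x, prior_alpha = 0.1, prior_beta = 1) {
  if (!length(x)) stop("need >= 1 sample", call. = FALSE)
  assert_count(x, "counts")
  new_background_prior(prior_alpha + sum(x), prior_beta + length(x),
                       "site-specific")
}

#' Fit background priors for a panel from blank-sample counts
#'
#' Convenience wrapper: per-probe site-specific priors and per-type
#' moment-matched priors, separately for the duplex and single-strand
#' channels. Microsatellite/homopolymer-flagged probes are excluded from the
#' type-level priors by default (their slippage-driven error rates are not
#' representative of the type).
#'
#' @param counts molecule-count table restricted to blank samples.
#' @param panel panel table with `probe_id`, `substitution_type`, `ms_flag`.
#' @param exclude_ms drop MS-flagged probes from type priors (default TRUE).
#' @return list with `site` (data frame of per-probe alpha/beta for both
#'   channels) and `type` (data frame per substitution type and channel).
#' @export
fit_background_model <- function(counts, panel, exclude_ms = TRUE) {
  site_one <- function(col) {
    agg <- tapply(counts[[col]], counts$probe_id, function(x) {
      p <- site_prior(x)
      c(p$alpha, p$beta, mean(x))
    })
    t(vapply(agg, identity, numeric(3)))
  }
  dup <- site_one("duplex_alt")
  ss <- site_one("single_strand_alt")
  probes <- rownames(dup)
  site <- data.frame(
    probe_id = probes,
    alpha_duplex = dup[, 1], beta_duplex = dup[, 2], rate_duplex = dup[, 3],
    alpha_single = ss[, 1], beta_single = ss[, 2], rate_single = ss[, 3],
    stringsAsFactors = FALSE)
  rownames(site) <- NULL
  site$substitution_type <-
    panel$substitution_type[match(site$probe_id, panel$probe_id)]
  site$ms_flag <- panel$ms_flag[match(site$probe_id, panel$probe_id)]

  use <- if (exclude_ms) !site$ms_flag else rep(TRUE, nrow(site))
  type_rows <- list()
  for (ty in unique(site$substitution_type[use])) {
    sel <- use & site$substitution_type == ty
    if (sum(sel) < 2L) next
    for (ch in c("duplex", "single")) {
      pr <- tryCatch(type_prior(site[[paste0("rate_", ch)]][sel], ty),
                     error = function(e) NULL)
      if (is.null(pr)) next
      type_rows[[length(type_rows) + 1L]] <- data.frame(
        substitution_type = ty, channel = ch,
        alpha = pr$alpha, beta = pr$beta, n_probes = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  list(site = site, type = do.call(rbind, type_rows))
}
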