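# Internal numerical and validation helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed.
#'
#' Each simulation stage (panel, counts, reads, ...) consumes its own seed so
#' stages can be regenerated independently. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(panel = 11L, counts = 101L, reads = 1009L, scorer = 5003L,
               folds = 20011L, misc = 300007L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  (as.integer(seed) %% 1000000L) * 2011L + offsets[[stream]]
}

assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (any(!is.finite(x)) || any(!lo_ok) || any(!hi_ok)) {
    stop(name, " must be a fraction in ", if (open_left) "(" else "[", "0,1",
         if (open_right) ")" else "]", call. = FALSE)
  }
  invisible(x)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(name, " must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (any(!is.finite(x)) || any(x < min) || any(x != round(x))) {
    stop(name, " must be an integer count >= ", min, call. = FALSE)
  }
  invisible(x)
}

geometric_mean <- function(x) exp(mean(log(x)))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log-density of a count under a Poisson whose rate is a fixed signal mean
#' plus a Gamma-distributed background rate.
#'
#' If `X ~ Poisson(s + lambda)` with `lambda ~ Gamma(alpha, rate = beta)`, the
#' marginal is the convolution of `Poisson(s)` with a negative binomial
#' `NB(size = alpha, prob = beta/(beta + 1))`. Evaluated exactly by summing
#' over the split of `x` between the two components; `s` may be a vector
#' (e.g. a posterior grid of signal means).
#'
#' @param x single non-negative integer count.
#' @param s vector of non-negative signal means.
#' @param alpha,beta Gamma background prior (rate parameterization); use
#'   `alpha = 0` for "no background".
#' @return vector of log-densities, one per element of `s`.
#' @keywords internal
#' @noRd
dpois_gamma_bg <- function(x, s, alpha, beta) {
  stopifnot(length(x) == 1L, x >= 0, x == round(x))
  if (alpha <= 0) return(stats::dpois(x, s, log = TRUE))
  p <- beta / (beta + 1)
  if (x == 0) return(-s + alpha * log(p))
  j <- 0:x
  # log P(signal part = j) over the grid of s: (length(s) x (x+1))
  lp_sig <- outer(s, j, function(si, jj) stats::dpois(jj, si, log = TRUE))
  lp_bg <- stats::dnbinom(x - j, size = alpha, prob = p, log = TRUE)
  M <- lp_sig + rep(lp_bg, each = length(s))
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  log(rowSums(exp(M - m))) + m
}

#' As dpois_gamma_bg, but with a Gamma-distributed signal rate: the count is
#' `X = S + B` with `S ~ Poisson(r k)`, `r ~ Gamma(a_r, b_r)` (so S is
#' negative binomial with size `a_r`, prob `b_r / (b_r + k)`) and `B` the
#' Gamma-background negative binomial. Used to propagate calibration
#' uncertainty of a probe's performance into the VAF posterior.
#' @keywords internal
#' @noRd
dnbinom_gamma_bg <- function(x, k, a_r, b_r, alpha, beta) {
  stopifnot(length(x) == 1L, x >= 0, x == round(x))
  p_sig <- b_r / (b_r + k)
  if (alpha <= 0) {
    return(stats::dnbinom(x, size = a_r, prob = p_sig, log = TRUE))
  }
  p_bg <- beta / (beta + 1)
  if (x == 0) return(a_r * log(p_sig) + alpha * log(p_bg))
  j <- 0:x
  lp_sig <- outer(p_sig, j, function(pp, jj) {
    stats::dnbinom(jj, size = a_r, prob = pp, log = TRUE)
  })
  lp_bg <- stats::dnbinom(x - j, size = alpha, prob = p_bg, log = TRUE)
  M <- lp_sig + rep(lp_bg, each = length(p_sig))
  m <- M[cbind(seq_len(nrow(M)), max.col(M, ties.method = "first"))]
  log(rowSums(exp(M - m))) + m
}

#' Upper-tail P(X >= k) under the Gamma-marginalised Poisson (negative
#' binomial) background model, or a fixed-rate Poisson when `lambda` is given.
#' @keywords internal
#' @noRd
background_tail <- function(k, alpha = NULL, beta = NULL, lambda = NULL) {
  stopifnot(k >= 0)
  if (k == 0) return(1)
  if (!is.null(lambda)) {
    stats::ppois(k - 1, lambda, lower.tail = FALSE)
  } else {
    stats::pnbinom(k - 1, size = alpha, prob = beta / (beta + 1),
                   lower.tail = FALSE)
  }
}
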