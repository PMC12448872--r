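# Selectivity calculus: per-probe and global selectivity, enrichment factor,
# relative sequencing amount, the selectivity categories, and the theoretical
# LoD / sequencing-depth calculators for panel-size comparisons.

#' Assay selectivity from recovered molecule counts
#'
#' `S = (1 - f) * m / (f * w)`: the ratio of the fraction of input alternate
#' molecules recovered to the fraction of input wild-type molecules
#' recovered. `S = 1` for a non-selective assay; `S > 1` indicates
#' enrichment of the targeted allele. Independent of the input VAF under
#' proportional recovery.
#'
#' @param m recovered alternate (variant) molecule count.
#' @param w recovered wild-type molecule count.
#' @param f input VAF, strictly inside (0, 1).
#' @return selectivity value(s); `NA` where `w == 0` (undefined, excluded
#'   from means downstream).
#' @export
#' @examples
#' selectivity(26, 12, 0.005)  # ~431
selectivity <- function(m, w, f) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    stop("f must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(m < 0) || any(w < 0)) stop("counts must be >= 0", call. = FALSE)
  ifelse(w == 0, NA_real_, (1 - f) * m / (f * w))
}

#' Per-probe selectivity averaged across qualifying samples
#'
#' Per-sample selectivity values are averaged (arithmetic mean) across all
#' samples with input VAF of at least `min_vaf` for each probe. Samples with
#' zero recovered wild-type molecules are excluded (selectivity undefined).
#'
#' @param counts molecule-count table with `probe_id, sample_id, total_alt,
#'   total_wt` (e.g. from [simulate_counts()] or [count_molecules()]).
#' @param samples sample table with `sample_id` and `vaf`.
#' @param min_vaf minimum qualifying input VAF (default 0.001, i.e. 0.1%).
#' @return data frame `probe_id, selectivity, n_samples` (`NA` selectivity
#'   when no sample qualifies).
#' @export
probe_selectivity <- function(counts, samples, min_vaf = 0.001) {
  vaf <- samples$vaf[match(counts$sample_id, samples$sample_id)]
  keep <- !is.na(vaf) & vaf >= min_vaf & vaf < 1
  x <- counts[keep, ]
  s <- selectivity(x$total_alt, x$total_wt, vaf[keep])
  agg <- tapply(s, x$probe_id, function(v) mean(v, na.rm = TRUE))
  n <- tapply(s, x$probe_id, function(v) sum(!is.na(v)))
  probes <- unique(counts$probe_id)
  out <- data.frame(probe_id = probes,
                    selectivity = as.numeric(agg[probes]),
                    n_samples = as.integer(ifelse(is.na(n[probes]), 0L,
                                                  n[probes])),
                    stringsAsFactors = FALSE)
  out$selectivity[is.nan(out$selectivity) | out$n_samples == 0L] <- NA_real_
  rownames(out) <- NULL
  out
}

#' Global (panel-wide) selectivity
#'
#' Selectivity computed on counts aggregated across all probes within each
#' qualifying sample, then averaged across samples. Within a sample the
#' aggregate value equals the harmonic mean of the per-probe selectivities
#' weighted by each probe's recovered alternate molecules (an algebraic
#' identity, tested).
#'
#' @inheritParams probe_selectivity
#' @return list with `S_g` (scalar global selectivity), and `per_sample`
#'   (data frame of per-sample aggregate values).
#' @export
global_selectivity <- function(counts, samples, min_vaf = 0.001) {
  vaf <- samples$vaf[match(counts$sample_id, samples$sample_id)]
  keep <- !is.na(vaf) & vaf >= min_vaf & vaf < 1
  x <- counts[keep, ]
  m <- tapply(x$total_alt, x$sample_id, sum)
  w <- tapply(x$total_wt, x$sample_id, sum)
  ids <- names(m)
  f <- samples$vaf[match(ids, samples$sample_id)]
  s <- selectivity(as.numeric(m), as.numeric(w), f)
  per_sample <- data.frame(sample_id = ids, vaf = f,
                           selectivity = s, stringsAsFactors = FALSE)
  rownames(per_sample) <- NULL
  list(S_g = mean(s, na.rm = TRUE), per_sample = per_sample)
}

#' Enrichment factor implied by a global selectivity
#'
#' `EF = S_g / (1 - f_i + f_i * S_g)`: the ratio of output over input VAF for
#' an assay with global selectivity `S_g` at input VAF `f_i`.
#'
#' @param S_g global selectivity (> 0).
#' @param f_i input VAF in (0, 1).
#' @export
#' @examples
#' enrichment_factor(31, 0.01)  # ~23.8
enrichment_factor <- function(S_g, f_i) {
  assert_positive(S_g, "S_g")
  assert_fraction(f_i, "f_i", open_left = TRUE, open_right = TRUE)
  S_g / (1 - f_i + f_i * S_g)
}

#' Relative sequencing amount and percent depth reduction
#'
#' `c_r = 1 / EF`: the fraction of a conventional (non-selective) assay's
#' sequencing depth needed to produce equivalent data at input VAF `f_i`;
#' the reduction is `(1 - c_r) * 100`%.
#'
#' @inheritParams enrichment_factor
#' @return list with `c_r` and `reduction_percent`.
#' @export
#' @examples
#' relative_sequencing(44.5, 0.01)$reduction_percent  # 96.8
relative_sequencing <- function(S_g, f_i) {
  c_r <- 1 / enrichment_factor(S_g, f_i)
  list(c_r = c_r, reduction_percent = (1 - c_r) * 100)
}

#' Classify a selectivity value into the standard categories
#'
#' Intervals: nonselective `[0, 1]`, weakly selective `(1, 10]`, selective
#' `(10, 50]`, strongly selective `> 50`.
#'
#' @param S selectivity value(s), >= 0.
#' @return factor with the four category levels.
#' @export
classify_selectivity <- function(S) {
  if (any(S < 0, na.rm = TRUE)) stop("S must be >= 0", call. = FALSE)
  cut(S, breaks = c(0, 1, 10, 50, Inf),
      labels = c("nonselective", "weakly selective", "selective",
                 "strongly selective"),
      right = TRUE, include.lowest = TRUE)
}

#' Theoretical limit of detection of a tumour-informed assay
#'
#' Solves `0.95 = 1 - Poisson(0; tcf * copies * n_variants)` for the tumour
#' cell fraction `tcf`, i.e. the fraction at which at least one tumour-derived
#' molecule is present across all tracked variants in 95% of samples,
#' assuming perfect detection: `tcf = ln(20) / (copies * n_variants)`.
#'
#' @param n_variants number of tracked variants.
#' @param haploid_copies haploid genome copies in the input (default 6060,
#'   about 20 ng).
#' @return theoretical LoD as a tumour fraction in parts per million.
#' @export
#' @examples
#' theoretical_lod(1800)  # ~0.27 ppm
#' theoretical_lod(50)    # ~10 ppm
theoretical_lod <- function(n_variants, haploid_copies = 6060) {
  assert_count(n_variants, "n_variants", min = 1L)
  assert_positive(haploid_copies, "haploid_copies")
  log(20) / (haploid_copies * n_variants) * 1e6
}

#' Theoretical sequencing depth of a panel
#'
#' `n_variants * reads_per_variant * nt_per_read_pair / 1e9` gigabases,
#' optionally divided by a panel-wide enrichment factor for a selective assay.
#'
#' @param n_variants number of tracked variants.
#' @param reads_per_variant target depth per variant (default 100000).
#' @param nt_per_read_pair nucleotides per read pair (default 300, i.e.
#'   2 x 150 bp).
#' @param enrichment panel-wide enrichment factor (>= 1; default 1,
#'   non-selective).
#' @return required sequencing in gigabases.
#' @export
#' @examples
#' theoretical_depth(1800)                    # 54 Gb
#' theoretical_depth(1800, enrichment = 23.8) # ~2.27 Gb
theoretical_depth <- function(n_variants, reads_per_variant = 1e5,
                              nt_per_read_pair = 300, enrichment = 1) {
  assert_count(n_variants, "n_variants", min = 1L)
  if (enrichment < 1) stop("enrichment must be >= 1", call. = FALSE)
  n_variants * reads_per_variant * nt_per_read_pair / 1e9 / enrichment
}
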