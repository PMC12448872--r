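# Sample-level quality control: failed-sample detection from control probes
# and cross-contamination detection from phased SNPs in blank samples.

#' Detect a failed (dropout) sample from its control probes
#'
#' A sample fails when fewer than `min_molecules` molecules are returned for
#' at least one control probe. Missing control data also fails the sample.
#'
#' @param control_counts named (or unnamed) vector of control-probe counts.
#' @param min_molecules failure threshold (default 100; note a count of
#'   exactly 100 passes).
#' @return list with `failed`, `failing_control_probes` and `note`.
#' @export
detect_failed_sample <- function(control_counts, min_molecules = 100) {
  if (!length(control_counts) || any(is.na(control_counts))) {
    return(list(failed = TRUE, failing_control_probes = character(0),
                note = "missing control-probe data"))
  }
  low <- control_counts < min_molecules
  nm <- names(control_counts) %||% as.character(seq_along(control_counts))
  list(failed = any(low),
       failing_control_probes = nm[low],
       note = if (any(low)) "control probe(s) below threshold" else "")
}

#' Phased-SNP contamination ratio
#'
#' Ratio of molecules carrying both the target variant and its phased SNP to
#' molecules carrying the original variant and covering the second site; an
#' approximation of the fraction of variant molecules derived from a
#' contaminating genome.
#'
#' @param n_both_snps molecules with both variants present.
#' @param n_covering molecules with the original variant covering the second
#'   site.
#' @return ratio in `[0, 1]`; `NA` when the denominator is 0.
#' @export
contamination_ratio <- function(n_both_snps, n_covering) {
  assert_count(n_both_snps, "n_both_snps")
  assert_count(n_covering, "n_covering")
  if (n_both_snps > n_covering) {
    stop("n_both_snps cannot exceed n_covering", call. = FALSE)
  }
  if (n_covering == 0) return(NA_real_)
  n_both_snps / n_covering
}

#' Flag a blank sample as cross-contaminated
#'
#' A blank is flagged only when both conditions hold: its aggregate alternate
#' duplex molecules exceed `molecule_threshold` (elevated apparent signal)
#' AND the phased-SNP contamination ratio exceeds `ratio_threshold`
#' (the signal is haplotype-linked to a foreign genome). Elevated background
#' without phased support is noted but not flagged.
#'
#' @param total_duplex_alt aggregate alternate duplex molecules in the blank.
#' @param ratio [contamination_ratio()] of the blank (`NA` treated as 0).
#' @param molecule_threshold default 8 (blank cohorts sit below 8 alternate
#'   duplex molecules).
#' @param ratio_threshold default 0.5 (contaminant-derived molecules must
#'   dominate).
#' @return list with `contaminated` and `note`.
#' @export
flag_contaminated <- function(total_duplex_alt, ratio,
                              molecule_threshold = 8, ratio_threshold = 0.5) {
  assert_count(total_duplex_alt, "total_duplex_alt")
  elevated <- total_duplex_alt > molecule_threshold
  linked <- !is.na(ratio) && ratio > ratio_threshold
  note <- if (elevated && !linked) {
    "elevated background without phased-SNP support"
  } else ""
  list(contaminated = elevated && linked, note = note)
}

#' QC report for every sample of a run
#'
#' Pure function of the count tables: failed-sample detection for all
#' samples, contamination assessment for blanks.
#'
#' @param run an `assay_run` (counts, controls, samples, contamination).
#' @param min_molecules control-probe failure threshold.
#' @param molecule_threshold,ratio_threshold see [flag_contaminated()].
#' @return data frame, one row per sample: `sample_id, failed,
#'   failing_control_probes, contamination_ratio, contaminated, note`.
#' @export
qc_report <- function(run, min_molecules = 100, molecule_threshold = 8,
                      ratio_threshold = 0.5) {
  rows <- list()
  for (sid in run$samples$sample_id) {
    ctrl <- run$controls[run$controls$sample_id == sid, ]
    fail <- detect_failed_sample(
      stats::setNames(ctrl$count, ctrl$control_id), min_molecules)
    is_blank <- run$samples$vaf[run$samples$sample_id == sid] == 0
    ratio <- NA_real_
    contaminated <- FALSE
    note <- fail$note
    if (is_blank && !is.null(run$contamination)) {
      con <- run$contamination[run$contamination$sample_id == sid, ]
      if (nrow(con)) {
        ratio <- contamination_ratio(con$n_both_snps, con$n_covering)
        total_dup <- sum(run$counts$duplex_alt[run$counts$sample_id == sid])
        fl <- flag_contaminated(total_dup, ratio, molecule_threshold,
                                ratio_threshold)
        contaminated <- fl$contaminated
        if (nzchar(fl$note)) note <- paste(note, fl$note, sep = "; ")
      }
    }
    rows[[sid]] <- data.frame(
      sample_id = sid, failed = fail$failed,
      failing_control_probes = paste(fail$failing_control_probes,
                                     collapse = ","),
      contamination_ratio = ratio, contaminated = contaminated,
      note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
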