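# Synthetic assay generator: probe panels, dilution-series samples, per-probe
# molecule-count tables and (optionally) read-level records with the
# statistical structure the downstream analysis assumes.

SNV_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
INDEL_TYPES <- c("SDEL", "SINS", "MDEL", "MINS")
SUBSTITUTION_TYPES <- c(SNV_TYPES, INDEL_TYPES)

# Default substitution-type spectrum for SNV probes (deamination-dominated,
# roughly what somatic panels see).
DEFAULT_SNV_SPECTRUM <- c("C>A" = 0.10, "C>G" = 0.08, "C>T" = 0.35,
                          "T>A" = 0.08, "T>C" = 0.25, "T>G" = 0.14)

# Default Gamma(alpha, beta) priors on the per-probe duplex background error
# rate (expected error molecules per sample), by substitution type. Means are
# of order 1e-3 so a ~1600-probe SNV panel accumulates a handful of duplex
# background molecules per blank; C>T is elevated (deamination artefacts).
DEFAULT_ERROR_PRIORS <- list(
  "C>A" = c(0.4, 400), "C>G" = c(0.3, 600), "C>T" = c(0.6, 200),
  "T>A" = c(0.3, 600), "T>C" = c(0.5, 400), "T>G" = c(0.3, 600),
  "SDEL" = c(0.5, 250), "SINS" = c(0.5, 250),
  "MDEL" = c(0.5, 250), "MINS" = c(0.5, 250))

#' Map a probe design score to an expected overall recovery rate
#'
#' Logistic link from the design score to the per-molecule recovery
#' probability of the enrichment step, scaled by the library-preparation
#' efficiency. The link is anchored so that a probe scoring 200 has an
#' enrichment-step efficiency of 0.47, i.e. an overall recovery of
#' `0.40 * 0.47 = 0.188` at the default library efficiency (about 120 of the
#' 633 alternate molecules present in a 20 ng, 10% VAF input).
#'
#' @param score numeric design score(s).
#' @param library_efficiency fraction of input molecules surviving library
#'   preparation (default 0.40).
#' @param anchor_score,anchor_efficiency calibration point of the logistic:
#'   enrichment-step efficiency at `anchor_score` (defaults 200 -> 0.47).
#' @param slope logistic scale in score units (default 75).
#' @return expected fraction of input molecules recovered, same length as
#'   `score`.
#' @export
#' @examples
#' score_to_recovery(200)        # ~0.188 overall, i.e. 47% of the 40% library
#' score_to_recovery(c(100, 300))
score_to_recovery <- function(score, library_efficiency = 0.40,
                              anchor_score = 200, anchor_efficiency = 0.47,
                              slope = 75) {
  assert_fraction(library_efficiency, "library_efficiency", open_left = TRUE)
  s0 <- anchor_score - slope * stats::qlogis(anchor_efficiency)
  library_efficiency * stats::plogis((score - s0) / slope)
}

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_panel()], [simulate_counts()] and [simulate_reads()]. Defaults
#' describe a tumour-informed dilution-series study: 20 ng (20000 pg) input at
#' 3.158 pg per haploid genome (about 6333 haploid copies), a VAF ladder from
#' 10% down to 1 ppm plus blanks, four replicates per level, ~40% library
#' efficiency and a 90/10 SNV/InDel panel split.
#'
#' @param n_probes number of variant-targeting probes in the panel.
#' @param snv_fraction,indel_fraction panel composition; must sum to 1.
#' @param input_mass_pg DNA input into library preparation, picograms.
#' @param pg_per_haploid_genome picograms of DNA per haploid genome copy.
#' @param vaf_levels input VAF dilution ladder (0 = blank).
#' @param replicates_per_level samples simulated per VAF level.
#' @param library_efficiency fraction of molecules surviving library prep.
#' @param duplex_probability probability a recovered molecule yields a duplex
#'   (both-strand) consensus rather than a single-strand one.
#' @param sample_sd log-scale standard deviation of the per-sample scaling
#'   factor (log-normal with median 1).
#' @param error_prior_by_type named list mapping substitution type to
#'   `c(alpha, beta)` for the Gamma prior on the duplex background rate.
#' @param ss_to_duplex_error_ratio single-strand over duplex background error
#'   rate ratio (> 1; single-strand molecules lack duplex error correction).
#' @param dropout_probability probability a sample fails QC (at least one
#'   control probe forced below 100 molecules).
#' @param contamination `NULL`, or `list(fraction=, phased=TRUE, n_blanks=)`:
#'   that many blank samples receive molecules from a contaminating genome at
#'   the given dilution fraction, carrying a phased SNP when `phased`.
#' @param score_mean,score_sd,score_range design-score distribution of the
#'   panel (truncated normal).
#' @param recovery_jitter_sd log-scale probe-to-probe jitter of the true
#'   recovery rate around the score link.
#' @param selectivity_meanlog,selectivity_sdlog log-normal distribution of
#'   per-probe true selectivity (defaults give median 35, mean approximately
#'   90, matching observed panel-scale spreads).
#' @param snv_spectrum named probability vector over the six SNV types.
#' @param ms_fraction,snp_fraction fractions of probes flagged as targeting a
#'   microsatellite/homopolymer context or overlapping a known SNP.
#' @param ms_error_multiplier inflation of the background rate at MS-flagged
#'   probes (polymerase slippage).
#' @param n_control_probes control probes targeting germline variants.
#' @param control_efficiency recovery rate of control probes.
#' @param reads_per_strand,umi_length,umi_error_rate,umi_error_max_edits,
#'   breakpoint_jitter,fragment_min,fragment_max,umi_min_dist read-level
#'   generator settings (see [simulate_reads()]).
#' @param seed master seed; all sub-stages derive named sub-streams from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 1800,
                       snv_fraction = 0.90,
                       indel_fraction = 0.10,
                       input_mass_pg = 20000,
                       pg_per_haploid_genome = 3.158,
                       vaf_levels = c(0.1, 0.01, 0.001, 1e-4, 1e-5, 1e-6, 0),
                       replicates_per_level = 4,
                       library_efficiency = 0.40,
                       duplex_probability = 0.5,
                       sample_sd = 0.15,
                       error_prior_by_type = DEFAULT_ERROR_PRIORS,
                       ss_to_duplex_error_ratio = 10,
                       dropout_probability = 0.125,
                       contamination = NULL,
                       score_mean = 240, score_sd = 50,
                       score_range = c(60, 400),
                       recovery_jitter_sd = 0.2,
                       selectivity_meanlog = log(35),
                       selectivity_sdlog = 1.4,
                       snv_spectrum = DEFAULT_SNV_SPECTRUM,
                       ms_fraction = 0.02,
                       snp_fraction = 0.02,
                       ms_error_multiplier = 25,
                       n_control_probes = 5,
                       control_efficiency = 0.19,
                       reads_per_strand = 2,
                       umi_length = 8,
                       umi_error_rate = 0,
                       umi_error_max_edits = 2,
                       breakpoint_jitter = 20,
                       fragment_min = 120,
                       fragment_max = 180,
                       umi_min_dist = 5,
                       seed = 1L) {
  assert_count(n_probes, "n_probes", min = 1L)
  assert_fraction(snv_fraction, "snv_fraction")
  assert_fraction(indel_fraction, "indel_fraction")
  if (abs(snv_fraction + indel_fraction - 1) > 1e-9) {
    stop("snv_fraction + indel_fraction must equal 1", call. = FALSE)
  }
  assert_positive(input_mass_pg, "input_mass_pg")
  assert_positive(pg_per_haploid_genome, "pg_per_haploid_genome")
  assert_fraction(vaf_levels, "vaf_levels")
  assert_count(replicates_per_level, "replicates_per_level", min = 1L)
  assert_fraction(library_efficiency, "library_efficiency", open_left = TRUE)
  assert_fraction(duplex_probability, "duplex_probability", open_left = TRUE)
  assert_fraction(dropout_probability, "dropout_probability")
  if (sample_sd < 0) stop("sample_sd must be >= 0", call. = FALSE)
  if (ss_to_duplex_error_ratio < 1) {
    stop("ss_to_duplex_error_ratio must be >= 1", call. = FALSE)
  }
  missing_types <- setdiff(SUBSTITUTION_TYPES, names(error_prior_by_type))
  if (length(missing_types)) {
    stop("error_prior_by_type missing types: ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  for (pr in error_prior_by_type) {
    # alpha = 0 encodes an error-free probe class (point mass at rate 0)
    if (length(pr) != 2L || pr[1] < 0 || pr[2] <= 0) {
      stop("error priors must be c(alpha >= 0, beta > 0)", call. = FALSE)
    }
  }
  if (!is.null(contamination)) {
    assert_fraction(contamination$fraction, "contamination$fraction",
                    open_left = TRUE)
    contamination$phased <- isTRUE(contamination$phased %||% TRUE)
    contamination$n_blanks <- as.integer(contamination$n_blanks %||% 1L)
  }
  snv_spectrum <- snv_spectrum / sum(snv_spectrum)
  if (!setequal(names(snv_spectrum), SNV_TYPES)) {
    stop("snv_spectrum must name exactly the six SNV types", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Haploid genome copies implied by a configuration
#' @param config a `sim_config`.
#' @return `input_mass_pg / pg_per_haploid_genome` (about 6333 at defaults).
#' @export
haploid_copies <- function(config) {
  config$input_mass_pg / config$pg_per_haploid_genome
}

rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < range[1] | x > range[2])) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Simulate a probe panel with its generative truth
#'
#' Draws a panel of `n_probes` probes: substitution types from the configured
#' spectrum (InDels split equally over SDEL/SINS/MDEL/MINS, lengths <= 40),
#' design scores from a truncated normal, true recovery rates via
#' [score_to_recovery()] with per-probe log-normal jitter, per-probe true
#' selectivity, and per-probe duplex/single-strand background error rates
#' drawn once from the substitution-type Gamma priors (inflated at
#' microsatellite-flagged probes). Control probes are generated alongside.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (probe table), `truth` (per-probe generative
#'   parameters), and `controls` (control-probe table with expected reference
#'   counts).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "panel"))
  n <- config$n_probes
  n_snv <- round(n * config$snv_fraction)
  n_indel <- n - n_snv

  types <- character(n)
  if (n_snv > 0) {
    types[seq_len(n_snv)] <- sample(names(config$snv_spectrum), n_snv,
                                    replace = TRUE, prob = config$snv_spectrum)
  }
  if (n_indel > 0) {
    # equal split over the four InDel classes, remainder to the first classes
    base <- n_indel %/% 4L
    extra <- n_indel %% 4L
    per_class <- rep(base, 4L) + (seq_len(4L) <= extra)
    types[n_snv + seq_len(n_indel)] <- rep(INDEL_TYPES, per_class)
  }
  is_indel <- types %in% INDEL_TYPES
  indel_length <- ifelse(types %in% c("SDEL", "SINS"), 1L,
                         ifelse(types %in% c("MDEL", "MINS"),
                                sample(2:40, n, replace = TRUE), 0L))

  score <- rnorm_trunc(n, config$score_mean, config$score_sd,
                       config$score_range)
  epsilon <- score_to_recovery(score, config$library_efficiency) *
    exp(stats::rnorm(n, 0, config$recovery_jitter_sd))
  epsilon <- pmin(epsilon, config$library_efficiency)
  selectivity <- stats::rlnorm(n, config$selectivity_meanlog,
                               config$selectivity_sdlog)

  ms_flag <- stats::runif(n) < config$ms_fraction
  snp_flag <- stats::runif(n) < config$snp_fraction

  prior_mat <- do.call(rbind, config$error_prior_by_type[types])
  lambda_duplex <- ifelse(prior_mat[, 1] == 0, 0,
                          stats::rgamma(n, shape = pmax(prior_mat[, 1], 1e-12),
                                        rate = prior_mat[, 2]))
  lambda_duplex <- lambda_duplex *
    ifelse(ms_flag, config$ms_error_multiplier, 1)
  lambda_single <- lambda_duplex * config$ss_to_duplex_error_ratio

  probe_id <- sprintf("probe_%04d", seq_len(n))
  panel <- data.frame(
    probe_id = probe_id,
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    variant_class = ifelse(is_indel, "InDel", "SNV"),
    substitution_type = types,
    indel_length = indel_length,
    score = score,
    ms_flag = ms_flag,
    snp_flag = snp_flag,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    probe_id = probe_id,
    epsilon = epsilon,
    selectivity = selectivity,
    lambda_duplex = lambda_duplex,
    lambda_single = lambda_single,
    stringsAsFactors = FALSE)
  controls <- data.frame(
    control_id = sprintf("control_%02d", seq_len(config$n_control_probes)),
    efficiency = config$control_efficiency,
    reference_count = config$control_efficiency * haploid_copies(config),
    stringsAsFactors = FALSE)
  list(panel = panel, truth = truth, controls = controls)
}

#' Simulate per-probe molecule-count tables for a dilution series
#'
#' For sample `i` with input VAF `f`, scaling `s_i` and haploid copies
#' `C = input_mass_pg / pg_per_haploid_genome`: recovered alternate molecules
#' are `Poisson(s_i * eps_p * C * f)` and wild-type molecules
#' `Poisson(s_i * (eps_p / S_p) * C * (1 - f))`; each recovered molecule is a
#' duplex with probability `duplex_probability`, else single-strand.
#' Background alternate errors are added as `Poisson(lambda_duplex)` and
#' `Poisson(lambda_single)` draws with the per-probe lambdas fixed in `truth`.
#' Control-probe counts are VAF-independent; dropout samples have at least one
#' control probe forced below 100 molecules; contaminated blanks receive
#' molecules carrying both the target variant and a phased SNP.
#'
#' @param panel output of [simulate_panel()] (or its `panel` element, with
#'   `truth` and `controls` supplied separately).
#' @param truth,controls per-probe truth and control table if `panel` is a
#'   bare data frame.
#' @param config the [sim_config()] used for the panel.
#' @return list of class `assay_run`: `counts` (one row per probe x sample),
#'   `controls` (long control counts), `samples` (per-sample truth: VAF,
#'   scaling, dropout and contamination flags), `contamination` (per-blank
#'   phased-SNP molecule tallies) and `copies`.
#' @export
simulate_counts <- function(panel, truth = NULL, config, controls = NULL) {
  if (is.list(panel) && !is.data.frame(panel) && !is.null(panel$panel)) {
    truth <- panel$truth
    controls <- panel$controls
    panel <- panel$panel
  }
  stopifnot(inherits(config, "sim_config"),
            identical(panel$probe_id, truth$probe_id))
  set.seed(substream_seed(config$seed, "counts"))

  C <- haploid_copies(config)
  d <- config$duplex_probability
  vaf <- rep(config$vaf_levels, each = config$replicates_per_level)
  n_samples <- length(vaf)
  samples <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n_samples)),
    vaf = vaf,
    scaling = stats::rlnorm(n_samples, 0, config$sample_sd),
    dropout = stats::runif(n_samples) < config$dropout_probability,
    contaminated = FALSE,
    stringsAsFactors = FALSE)
  if (!is.null(config$contamination)) {
    blanks <- which(samples$vaf == 0)
    pick <- blanks[seq_len(min(config$contamination$n_blanks, length(blanks)))]
    samples$contaminated[pick] <- TRUE
  }

  n_probes <- nrow(panel)
  counts_list <- vector("list", n_samples)
  contam_list <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    f <- samples$vaf[i]
    s_i <- samples$scaling[i]
    mu_alt <- s_i * truth$epsilon * C * f
    mu_wt <- s_i * (truth$epsilon / truth$selectivity) * C * (1 - f)
    n_alt <- stats::rpois(n_probes, mu_alt)
    n_wt <- stats::rpois(n_probes, mu_wt)
    dup_alt <- stats::rbinom(n_probes, n_alt, d)
    dup_wt <- stats::rbinom(n_probes, n_wt, d)
    err_dup <- stats::rpois(n_probes, truth$lambda_duplex)
    err_ss <- stats::rpois(n_probes, truth$lambda_single)

    contam_dup_snp <- 0L
    if (samples$contaminated[i]) {
      mu_con <- s_i * truth$epsilon * C * config$contamination$fraction
      n_con <- stats::rpois(n_probes, mu_con)
      dup_con <- stats::rbinom(n_probes, n_con, d)
      dup_alt <- dup_alt + dup_con
      n_alt <- n_alt + n_con
      if (config$contamination$phased) contam_dup_snp <- sum(dup_con)
    }
    duplex_alt <- dup_alt + err_dup
    single_alt <- (n_alt - dup_alt) + err_ss
    counts_list[[i]] <- data.frame(
      probe_id = panel$probe_id,
      sample_id = samples$sample_id[i],
      duplex_alt = duplex_alt,
      single_strand_alt = single_alt,
      duplex_wt = dup_wt,
      single_strand_wt = n_wt - dup_wt,
      stringsAsFactors = FALSE)
    if (samples$vaf[i] == 0) {
      # phased-SNP tallies used by the contamination QC: molecules with both
      # the variant and the linked SNP vs all duplex variant molecules that
      # cover the second site
      contam_list[[i]] <- data.frame(
        sample_id = samples$sample_id[i],
        n_both_snps = contam_dup_snp,
        n_covering = contam_dup_snp + sum(err_dup),
        stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(rbind, counts_list)
  counts$total_alt <- counts$duplex_alt + counts$single_strand_alt
  counts$total_wt <- counts$duplex_wt + counts$single_strand_wt

  ctrl_rate <- outer(samples$scaling, controls$reference_count)
  ctrl_counts <- matrix(stats::rpois(length(ctrl_rate), ctrl_rate),
                        nrow = n_samples)
  for (i in which(samples$dropout)) {
    j <- sample.int(nrow(controls), 1L)
    ctrl_counts[i, j] <- min(stats::rpois(1L, 0.02 * ctrl_rate[i, j]), 99L)
  }
  control_counts <- data.frame(
    sample_id = rep(samples$sample_id, times = nrow(controls)),
    control_id = rep(controls$control_id, each = n_samples),
    count = as.vector(ctrl_counts),
    stringsAsFactors = FALSE)
  control_counts <- control_counts[order(control_counts$sample_id,
                                         control_counts$control_id), ]
  rownames(control_counts) <- NULL

  structure(list(counts = counts,
                 controls = control_counts,
                 samples = samples,
                 contamination = do.call(rbind, contam_list),
                 copies = C),
            class = "assay_run")
}

random_umi <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_umi <- function(umi, n_edits) {
  s <- strsplit(umi, "")[[1]]
  pos <- sample.int(length(s), n_edits)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

#' Expand molecule counts into aligned-read records
#'
#' Each molecule becomes a read bundle: shared fragment breakpoints around the
#' probe's target position, one UMI, `reads_per_strand` reads per strand (both
#' strands iff the molecule is a duplex) and the variant or reference base at
#' the target position. Within a breakpoint group, molecule UMIs are kept at
#' pairwise Levenshtein distance >= `umi_min_dist` so that error-free records
#' round-trip exactly through [group_read_bundles()]. Optional per-read UMI
#' errors apply up to `umi_error_max_edits` substitutions with probability
#' `umi_error_rate`.
#'
#' @param run an `assay_run` from [simulate_counts()] (or a bare counts table).
#' @param panel panel table (for target coordinates); required when `run`
#'   lacks them.
#' @param config the [sim_config()].
#' @param sample_ids,probe_ids optional subsets to expand.
#' @return data frame of read records in the native dialect: `read_id, chrom,
#'   start, end, strand, umi, base_at_target, probe_id, sample_id`.
#' @export
simulate_reads <- function(run, panel, config,
                           sample_ids = NULL, probe_ids = NULL) {
  counts <- if (is.data.frame(run)) run else run$counts
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "reads"))
  if (!is.null(sample_ids)) counts <- counts[counts$sample_id %in% sample_ids, ]
  if (!is.null(probe_ids)) counts <- counts[counts$probe_id %in% probe_ids, ]
  pos <- panel$pos[match(counts$probe_id, panel$probe_id)]
  chrom <- panel$chrom[match(counts$probe_id, panel$probe_id)]

  out <- vector("list", nrow(counts))
  for (r in seq_len(nrow(counts))) {
    mols <- rep(c("duplex_alt", "single_alt", "duplex_wt", "single_wt"),
                c(counts$duplex_alt[r], counts$single_strand_alt[r],
                  counts$duplex_wt[r], counts$single_strand_wt[r]))
    n_mol <- length(mols)
    if (n_mol == 0) next
    start <- pos[r] - 1L - sample.int(config$breakpoint_jitter + 1L, n_mol,
                                      replace = TRUE) + 1L
    end <- start + sample(config$fragment_min:config$fragment_max, n_mol,
                          replace = TRUE)
    umi <- random_umi(n_mol, config$umi_length)
    # enforce UMI separation within identical-breakpoint groups
    grp <- paste(start, end)
    for (g in unique(grp[duplicated(grp)])) {
      idx <- which(grp == g)
      repeat {
        dmat <- utils::adist(umi[idx])
        clash <- which(dmat < config$umi_min_dist & upper.tri(dmat),
                       arr.ind = TRUE)
        if (nrow(clash) == 0) break
        redo <- unique(clash[, 2L])
        umi[idx[redo]] <- random_umi(length(redo), config$umi_length)
      }
    }
    is_dup <- grepl("^duplex", mols)
    is_alt <- grepl("alt$", mols)
    strands <- ifelse(is_dup, "both",
                      sample(c("top", "bottom"), n_mol, replace = TRUE))
    rows <- vector("list", n_mol)
    for (m in seq_len(n_mol)) {
      str_set <- if (strands[m] == "both") c("top", "bottom") else strands[m]
      strand <- rep(str_set, each = config$reads_per_strand)
      n_reads <- length(strand)
      u <- rep(umi[m], n_reads)
      if (config$umi_error_rate > 0) {
        hit <- stats::runif(n_reads) < config$umi_error_rate
        for (k in which(hit)) {
          u[k] <- mutate_umi(u[k],
                             sample.int(config$umi_error_max_edits, 1L))
        }
      }
      rows[[m]] <- data.frame(
        chrom = chrom[r], start = start[m], end = end[m], strand = strand,
        umi = u, base_at_target = if (is_alt[m]) "alt" else "ref",
        probe_id = counts$probe_id[r], sample_id = counts$sample_id[r],
        stringsAsFactors = FALSE)
    }
    out[[r]] <- do.call(rbind, rows)
  }
  reads <- do.call(rbind, out)
  if (is.null(reads)) {
    reads <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        umi = character(), base_at_target = character(),
                        probe_id = character(), sample_id = character(),
                        stringsAsFactors = FALSE)
  }
  reads <- cbind(read_id = sprintf("read_%06d", seq_len(nrow(reads))), reads,
                 stringsAsFactors = FALSE)
  reads
}
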