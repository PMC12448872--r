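# Probe design: candidate enumeration around a variant, sequence features
# (melting temperature, GC, lengths, 3'-end geometry, SNP and repeat flags),
# pluggable scoring, best-design selection and panel sampling.

# Unified nearest-neighbour thermodynamic parameters (dH kcal/mol, dS cal/K/mol)
# for DNA/DNA duplexes, with terminal initiation terms.
NN_DH <- c("AA" = -7.9, "AT" = -7.2, "TA" = -7.2, "CA" = -8.5, "GT" = -8.4,
           "CT" = -7.8, "GA" = -8.2, "CG" = -10.6, "GC" = -9.8, "GG" = -8.0)
NN_DS <- c("AA" = -22.2, "AT" = -20.4, "TA" = -21.3, "CA" = -22.7,
           "GT" = -22.4, "CT" = -21.0, "GA" = -22.2, "CG" = -27.2,
           "GC" = -24.4, "GG" = -19.9)
NN_INIT_AT <- c(dH = 2.3, dS = 4.1)
NN_INIT_GC <- c(dH = 0.1, dS = -2.8)

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", vapply(strsplit(seq, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1)))
}

#' Nearest-neighbour melting temperature of a DNA oligo
#'
#' Unified nearest-neighbour model with terminal initiation terms, an
#' entropic monovalent-salt correction of `0.368 (N - 1) ln[Na+]` and
#' `Tm = 1000 dH / (dS + R ln(C_T)) - 273.15` with `R = 1.987` cal/K/mol.
#' Defaults: 50 mM Na+, 250 nM excess single strand. Deterministic; a
#' sequence and its reverse complement give identical values.
#'
#' @param sequence DNA string(s) over `{A,C,G,T}`, length >= 8.
#' @param Na monovalent cation concentration, mM.
#' @param oligo_nM excess single-strand concentration, nM.
#' @return melting temperature(s) in degrees Celsius.
#' @export
melting_temperature <- function(sequence, Na = 50, oligo_nM = 250) {
  vapply(toupper(sequence), function(s) {
    if (!grepl("^[ACGT]+$", s)) {
      stop("sequence must contain only A/C/G/T (no ambiguity codes)",
           call. = FALSE)
    }
    n <- nchar(s)
    if (n < 8) stop("sequence must be at least 8 nt", call. = FALSE)
    b <- strsplit(s, "")[[1]]
    dh <- 0
    ds <- 0
    for (end in c(b[1L], b[n])) {
      init <- if (end %in% c("A", "T")) NN_INIT_AT else NN_INIT_GC
      dh <- dh + init[["dH"]]
      ds <- ds + init[["dS"]]
    }
    pairs <- paste0(b[-n], b[-1L])
    # table stores one orientation per stack; fall back to the reverse
    # complement of the dinucleotide for the missing ones
    key <- ifelse(pairs %in% names(NN_DH), pairs,
                  chartr("ACGT", "TGCA",
                         vapply(strsplit(pairs, ""),
                                function(p) paste(rev(p), collapse = ""),
                                character(1))))
    dh <- dh + sum(NN_DH[key])
    ds <- ds + sum(NN_DS[key])
    ds <- ds + 0.368 * (n - 1) * log(Na / 1000)
    1000 * dh / (ds + 1.987 * log(oligo_nM * 1e-9)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Construct a variant target
#'
#' @param chrom,pos 1-based variant position.
#' @param ref,alt alleles.
#' @param context sequence context containing the variant.
#' @param context_offset 1-based position of the variant's first base within
#'   `context`.
#' @param snp_offsets offsets (bases, relative to the variant, signed) of
#'   known nearby SNPs.
#' @return list of class `variant_target` with the derived variant class
#'   (substitution type for SNVs, SDEL/SINS/MDEL/MINS for InDels).
#' @export
variant_target <- function(chrom, pos, ref, alt, context,
                           context_offset = (nchar(context) + 1) %/% 2,
                           snp_offsets = integer(0)) {
  cls <- classify_variant(ref, alt)
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = cls, context = toupper(context),
                 context_offset = context_offset,
                 snp_offsets = snp_offsets),
            class = "variant_target")
}

#' Classify a variant by its alleles
#'
#' SNVs map to the six pyrimidine-context substitution types (purine refs are
#' complemented); indels to SDEL/SINS (single-base) or MDEL/MINS
#' (multi-base).
#'
#' @param ref,alt allele strings.
#' @return substitution-type string.
#' @export
classify_variant <- function(ref, alt) {
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt)) {
    stop("symbolic or ambiguous alleles are not supported", call. = FALSE)
  }
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    if (ref %in% c("G", "A")) {
      ref <- chartr("GA", "CT", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    return(paste0(ref, ">", alt))
  }
  if (nchar(ref) > nchar(alt)) {
    if (nchar(ref) - nchar(alt) == 1L) "SDEL" else "MDEL"
  } else if (nchar(alt) > nchar(ref)) {
    if (nchar(alt) - nchar(ref) == 1L) "SINS" else "MINS"
  } else {
    stop("multi-nucleotide substitutions are not supported", call. = FALSE)
  }
}

#' Enumerate candidate probe designs around a variant
#'
#' One candidate per (upstream length, downstream length) pair: the probe
#' covers `upstream` bases 5' of the variant, the variant itself, and
#' `downstream` bases 3' of it, so the variant sits `downstream` bases from
#' the probe's 3' end. Optionally the reverse-complement designs are added.
#'
#' @param target a [variant_target()].
#' @param upstream,downstream integer ranges of flank lengths.
#' @param both_strands also emit reverse-complement designs (default FALSE).
#' @return data frame of candidates with sequence, lengths and strand.
#' @export
enumerate_candidates <- function(target, upstream = 20:60, downstream = 3:10,
                                 both_strands = FALSE) {
  stopifnot(inherits(target, "variant_target"))
  off <- target$context_offset
  vlen <- nchar(target$ref)
  need_left <- max(upstream)
  need_right <- max(downstream)
  if (off - need_left < 1 ||
      off + vlen - 1 + need_right > nchar(target$context)) {
    stop(sprintf(
      "context too short: need %d bases upstream and %d downstream of the variant",
      need_left, need_right), call. = FALSE)
  }
  grid <- expand.grid(upstream = upstream, downstream = downstream)
  seqs <- substr(rep(target$context, nrow(grid)),
                 off - grid$upstream, off + vlen - 1 + grid$downstream)
  out <- data.frame(sequence = seqs,
                    upstream = grid$upstream, downstream = grid$downstream,
                    strand = "+", stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- out
    rc$sequence <- revcomp(out$sequence)
    rc$strand <- "-"
    # on the minus strand the roles of the flanks swap
    rc$upstream <- out$downstream
    rc$downstream <- out$upstream
    out <- rbind(out, rc)
  }
  out$length <- nchar(out$sequence)
  out
}

gc_content <- function(sequence) {
  vapply(strsplit(toupper(sequence), ""), function(b) {
    mean(b %in% c("G", "C"))
  }, numeric(1))
}

has_repeat_context <- function(context, offset, window = 15) {
  lo <- max(1, offset - window)
  hi <- min(nchar(context), offset + window)
  w <- substr(context, lo, hi)
  grepl("A{6,}|C{6,}|G{6,}|T{6,}", w) ||
    grepl("([ACGT]{2,6})\\1{2,}", w, perl = TRUE)
}

#' Compute the design feature vector of candidate probes
#'
#' Features: melting temperature, total/upstream/downstream lengths, GC
#' content, variant offset from the 3' end, whether a known SNP falls within
#' 25 bp of the 3' end, a microsatellite/homopolymer flag (homopolymer run
#' >= 6 or >= 3 tandem copies of a 2-6-mer near the variant) and a low-GC
#' flag (< 0.35).
#'
#' @param designs data frame from [enumerate_candidates()].
#' @param target the [variant_target()].
#' @return `designs` with feature columns appended.
#' @export
compute_features <- function(designs, target) {
  designs$tm <- melting_temperature(designs$sequence)
  designs$gc_content <- gc_content(designs$sequence)
  designs$variant_offset_3prime <- designs$downstream
  # SNP offsets are relative to the variant; distance to the probe 3' end is
  # downstream - offset for SNPs inside the probe span
  designs$snp_within_25bp_3prime <- vapply(seq_len(nrow(designs)),
    function(i) {
      if (!length(target$snp_offsets)) return(FALSE)
      inside <- target$snp_offsets >= -designs$upstream[i] &
        target$snp_offsets <= designs$downstream[i]
      any(inside & (designs$downstream[i] - target$snp_offsets) <= 25)
    }, logical(1))
  designs$ms_flag <- has_repeat_context(target$context, target$context_offset)
  designs$low_gc <- designs$gc_content < 0.35
  designs
}

# Latent design-quality surface used to generate scorer training data. Each
# term is in [0, 1]; scores land roughly on a 0-400 scale so the published
# per-type threshold semantics (median-or-threshold on the active scorer's
# scale) remain meaningful.
latent_design_score <- function(features) {
  gc_term <- pmin(pmax((features$gc_content - 0.20) / 0.25, 0), 1)
  tm_term <- exp(-((features$tm - 72) / 10)^2)
  off_term <- exp(-((features$variant_offset_3prime - 7) / 6)^2)
  len_term <- exp(-((features$length - 45) / 25)^2)
  40 + 140 * gc_term + 90 * tm_term + 60 * off_term + 50 * len_term -
    80 * features$snp_within_25bp_3prime - 120 * features$ms_flag
}

FEATURE_COLS <- c("tm", "length", "upstream", "downstream", "gc_content",
                  "variant_offset_3prime", "snp_within_25bp_3prime",
                  "ms_flag", "low_gc")

random_context <- function(len, gc = 0.45) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Train the bundled random-forest probe scorer on simulator-generated data
#'
#' Generates random variant targets with random sequence contexts,
#' enumerates candidate designs, computes features, assigns each design a
#' noisy observed score from the latent design-quality surface (emulating
#' scores derived from measured probe recovery), and fits a random forest
#' regression of observed score on the feature vector.
#'
#' @param n_targets number of random variant targets (default 60).
#' @param noise_sd score-scale observation noise (default 45).
#' @param holdout_fraction fraction of targets held out to report r^2.
#' @param seed RNG seed.
#' @return list of class `probe_scorer`: the fitted forest, the feature
#'   names, and `r_squared` on held-out designs.
#' @export
train_probe_scorer <- function(n_targets = 60, noise_sd = 35,
                               holdout_fraction = 0.25, seed = 1L) {
  set.seed(substream_seed(seed, "scorer"))
  feats <- list()
  tgt_id <- integer(0)
  for (t in seq_len(n_targets)) {
    ctx <- random_context(200, gc = stats::runif(1, 0.30, 0.60))
    tg <- variant_target("chr1", 1000L, substr(ctx, 100, 100),
                         sample(setdiff(c("A", "C", "G", "T"),
                                        substr(ctx, 100, 100)), 1),
                         context = ctx, context_offset = 100L,
                         snp_offsets = if (stats::runif(1) < 0.3) {
                           sample(-30:30, 1L)
                         } else integer(0))
    cand <- enumerate_candidates(tg, upstream = seq(20, 60, by = 8),
                                 downstream = seq(3, 12, by = 3))
    f <- compute_features(cand, tg)
    feats[[t]] <- f
    tgt_id <- c(tgt_id, rep(t, nrow(f)))
  }
  feats <- do.call(rbind, feats)
  score_obs <- latent_design_score(feats) +
    stats::rnorm(nrow(feats), 0, noise_sd)
  X <- feats[, FEATURE_COLS]
  X$snp_within_25bp_3prime <- as.numeric(X$snp_within_25bp_3prime)
  X$ms_flag <- as.numeric(X$ms_flag)
  X$low_gc <- as.numeric(X$low_gc)

  hold <- tgt_id %in% sample(n_targets, round(n_targets * holdout_fraction))
  fit <- randomForest::randomForest(X[!hold, ], score_obs[!hold],
                                    ntree = 400)
  pred <- stats::predict(fit, X[hold, ])
  r2 <- 1 - sum((score_obs[hold] - pred)^2) /
    sum((score_obs[hold] - mean(score_obs[hold]))^2)
  structure(list(fit = fit, features = FEATURE_COLS, r_squared = r2),
            class = "probe_scorer")
}

#' Score candidate designs with a pluggable scorer
#'
#' @param designs feature-annotated designs ([compute_features()]).
#' @param scorer either a `probe_scorer` or any function mapping the feature
#'   data frame to a numeric score vector.
#' @return `designs` with a `score` column.
#' @export
score_probes <- function(designs, scorer) {
  if (inherits(scorer, "probe_scorer")) {
    missing <- setdiff(scorer$features, names(designs))
    if (length(missing)) {
      stop("designs lack scorer features: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    X <- designs[, scorer$features]
    X$snp_within_25bp_3prime <- as.numeric(X$snp_within_25bp_3prime)
    X$ms_flag <- as.numeric(X$ms_flag)
    X$low_gc <- as.numeric(X$low_gc)
    designs$score <- as.numeric(stats::predict(scorer$fit, X))
  } else if (is.function(scorer)) {
    designs$score <- as.numeric(scorer(designs))
  } else {
    stop("scorer must be a probe_scorer or a function", call. = FALSE)
  }
  designs
}

#' Select the best design passing the melting-temperature filter
#'
#' Argmax of the score among designs with `tm >= tm_min`; ties broken by
#' shorter length, then lexicographically by sequence.
#'
#' @param designs scored designs.
#' @param tm_min minimum melting temperature (default 65).
#' @return the selected design row.
#' @export
select_best <- function(designs, tm_min = 65) {
  ok <- designs$tm >= tm_min
  if (!any(ok)) {
    stop(sprintf(
      "no design passes the Tm filter (best rejected Tm: %.1f < %.1f)",
      max(designs$tm), tm_min), call. = FALSE)
  }
  d <- designs[ok, ]
  d <- d[order(-d$score, d$length, d$sequence), ]
  d[1L, ]
}

#' Sample a clinically representative probe panel from a scored variant pool
#'
#' Honours the SNV/InDel composition (equal SDEL/SINS/MDEL/MINS split),
#' removes InDels longer than 40 bp, and in `pool2_mode` applies per-type
#' score thresholds (above each type's pool median by default, or explicit
#' thresholds on the active scorer's scale). Sampling is seeded.
#'
#' @param pool data frame with `variant_class` ("SNV"/"InDel"),
#'   `substitution_type`, `indel_length`, `score`.
#' @param size panel size.
#' @param snv_fraction fraction of SNV probes (default 0.9).
#' @param pool2_mode apply per-type score thresholds (default FALSE).
#' @param snv_threshold,indel_threshold explicit score thresholds for
#'   `pool2_mode` (default: the pool's per-type median).
#' @param max_indel_length default 40.
#' @param seed sampling seed.
#' @return the sampled panel rows.
#' @export
sample_panel <- function(pool, size, snv_fraction = 0.9, pool2_mode = FALSE,
                         snv_threshold = NULL, indel_threshold = NULL,
                         max_indel_length = 40, seed = 1L) {
  set.seed(substream_seed(seed, "panel"))
  pool <- pool[!(pool$variant_class == "InDel" &
                   pool$indel_length > max_indel_length), ]
  if (pool2_mode) {
    snv_thr <- snv_threshold %||%
      stats::median(pool$score[pool$variant_class == "SNV"])
    ind_thr <- indel_threshold %||%
      stats::median(pool$score[pool$variant_class == "InDel"])
    pool <- pool[(pool$variant_class == "SNV" & pool$score > snv_thr) |
                   (pool$variant_class == "InDel" & pool$score > ind_thr), ]
  }
  n_snv <- round(size * snv_fraction)
  n_indel <- size - n_snv
  snv_pool <- which(pool$variant_class == "SNV")
  if (length(snv_pool) < n_snv) {
    stop("pool has too few SNVs for the requested composition",
         call. = FALSE)
  }
  take <- sample(snv_pool, n_snv)
  if (n_indel > 0) {
    base <- n_indel %/% 4L
    extra <- n_indel %% 4L
    for (k in seq_along(INDEL_TYPES)) {
      want <- base + (k <= extra)
      avail <- which(pool$substitution_type == INDEL_TYPES[k])
      if (length(avail) < want) {
        stop("pool has too few ", INDEL_TYPES[k],
             " variants for the requested composition", call. = FALSE)
      }
      take <- c(take, sample(avail, want))
    }
  }
  out <- pool[take, ]
  rownames(out) <- NULL
  out
}
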