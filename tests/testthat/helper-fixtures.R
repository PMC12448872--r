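# Shared fixtures and independent oracles used across test files.

# A small, fast configuration for generator-backed tests.
small_config <- function(...) {
  args <- list(...)
  defaults <- list(n_probes = 40, replicates_per_level = 2,
                   vaf_levels = c(0.1, 0.01, 0), dropout_probability = 0,
                   seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Zero-background error priors (every substitution type error-free).
zero_priors <- function() {
  pr <- duplexmrd:::DEFAULT_ERROR_PRIORS
  lapply(pr, function(x) c(0, x[2]))
}

# Independent brute-force UMI clustering oracle: enumerate all pairs and
# transitively merge UMIs within the edit distance (union-find).
brute_force_umi_clusters <- function(umis, max_edit = 2) {
  uniq <- unique(umis)
  parent <- seq_along(uniq)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  d <- utils::adist(uniq)
  for (i in seq_along(uniq)) {
    for (j in seq_along(uniq)) {
      if (i < j && d[i, j] <= max_edit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(uniq), find, integer(1))
  match(roots, unique(roots))[match(umis, uniq)]
}

# Canonical representation of a partition for set-equality comparison.
partition_signature <- function(cluster_ids, items) {
  sort(unname(vapply(split(items, cluster_ids), function(s) {
    paste(sort(s), collapse = "|")
  }, character(1))))
}

# m-weighted harmonic mean of per-probe selectivities (terms with m = 0
# contribute nothing to either sum).
weighted_harmonic_selectivity <- function(m, w, f) {
  S <- (1 - f) * m / (f * w)
  keep <- m > 0
  sum(m[keep]) / sum(m[keep] / S[keep])
}

# Build a read table row-by-row for hand-constructed counter fixtures.
make_reads <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(chrom = r$chrom %||% "chr1", start = r$start %||% 100L,
               end = r$end %||% 250L, strand = r$strand,
               umi = r$umi, base_at_target = r$base %||% "alt",
               probe_id = r$probe %||% "p1", sample_id = r$sample %||% "s1",
               stringsAsFactors = FALSE)
  }))
  cbind(read_id = sprintf("r%03d", seq_len(nrow(df))), df,
        stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
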