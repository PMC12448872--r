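# UMI read-bundle grouping and duplex consensus molecule counting.
#
# Reads sharing identical fragment breakpoints and similar UMIs (Levenshtein
# distance <= 2 by default) are collapsed into read bundles; per-strand
# consensus alleles decide whether a bundle is counted as a duplex or
# single-strand molecule of the alternate or wild-type allele.

validate_reads <- function(reads) {
  needed <- c("read_id", "chrom", "start", "end", "strand", "umi",
              "base_at_target", "probe_id", "sample_id")
  missing <- setdiff(needed, names(reads))
  if (length(missing)) {
    stop("read table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(reads$start) | !is.finite(reads$end) |
                 reads$start >= reads$end)
  if (length(bad)) {
    stop("malformed coordinates (start >= end) for read_id: ",
         paste(utils::head(reads$read_id[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!grepl("^[ACGTN]+$", reads$umi))) {
    stop("UMIs must be non-empty strings over {A,C,G,T,N}", call. = FALSE)
  }
  invisible(reads)
}

#' Cluster the UMIs of one identical-breakpoint group
#'
#' Greedy seeded clustering on the Levenshtein adjacency graph: unique UMIs
#' are ordered by descending read support (ties broken lexicographically);
#' each unassigned seed absorbs, transitively, every unassigned UMI reachable
#' through edges of edit distance <= `max_edit_distance`. With transitive
#' absorption the partition equals the connected components of the adjacency
#' graph; the seed (highest-support member) is the cluster's canonical UMI.
#'
#' @param umis character vector of observed UMIs (one per read).
#' @param max_edit_distance Levenshtein collapse threshold (default 2).
#' @return integer cluster index per read, with canonical UMIs as the
#'   `canonical` attribute (indexed by cluster).
#' @export
cluster_umis <- function(umis, max_edit_distance = 2) {
  tab <- sort(table(umis), decreasing = TRUE)
  uniq <- names(tab)
  ord <- order(-as.integer(tab), uniq)
  uniq <- uniq[ord]
  n <- length(uniq)
  if (n == 1L) {
    cl <- rep(1L, length(umis))
    attr(cl, "canonical") <- uniq
    return(cl)
  }
  adj <- utils::adist(uniq) <= max_edit_distance
  assigned <- integer(n)
  canonical <- character(0)
  k <- 0L
  for (i in seq_len(n)) {
    if (assigned[i]) next
    k <- k + 1L
    canonical[k] <- uniq[i]
    frontier <- i
    assigned[i] <- k
    while (length(frontier)) {
      nxt <- which(!assigned & colSums(adj[frontier, , drop = FALSE]) > 0)
      assigned[nxt] <- k
      frontier <- nxt
    }
  }
  cl <- assigned[match(umis, uniq)]
  attr(cl, "canonical") <- canonical
  cl
}

#' Group aligned reads into UMI read bundles
#'
#' Reads are first grouped by identical breakpoints (sample, probe, chrom,
#' start, end); within each group UMIs are clustered with [cluster_umis()].
#' Each cluster becomes one read bundle, the unit later counted as a single
#' input molecule.
#'
#' @param reads read table in the native dialect (see [simulate_reads()]).
#' @param max_edit_distance Levenshtein collapse threshold (default 2).
#' @return list with `reads` (input annotated with `bundle_id`) and `bundles`
#'   (one row per bundle: breakpoints, canonical UMI, strands present, read
#'   count).
#' @export
group_read_bundles <- function(reads, max_edit_distance = 2) {
  validate_reads(reads)
  key <- paste(reads$sample_id, reads$probe_id, reads$chrom,
               reads$start, reads$end, sep = "\r")
  reads$bundle_id <- NA_character_
  canon <- character(0)
  groups <- split(seq_len(nrow(reads)), key)
  bid <- 0L
  bundle_rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    cl <- cluster_umis(reads$umi[idx], max_edit_distance)
    canon_g <- attr(cl, "canonical")
    ids <- sprintf("bundle_%06d", bid + seq_along(canon_g))
    reads$bundle_id[idx] <- ids[cl]
    first <- idx[!duplicated(cl)][order(unique(cl))]
    bundle_rows[[g]] <- data.frame(
      bundle_id = ids,
      sample_id = reads$sample_id[idx[1L]],
      probe_id = reads$probe_id[idx[1L]],
      chrom = reads$chrom[idx[1L]],
      start = reads$start[idx[1L]],
      end = reads$end[idx[1L]],
      canonical_umi = canon_g,
      n_reads = as.integer(tabulate(cl, length(canon_g))),
      stringsAsFactors = FALSE)
    bid <- bid + length(canon_g)
  }
  bundles <- do.call(rbind, bundle_rows)
  rownames(bundles) <- NULL
  list(reads = reads, bundles = bundles)
}

#' Per-strand consensus allele of a read bundle
#'
#' For each strand present, the majority allele among the member reads of
#' that strand, requiring at least a 2/3 majority; ties or sub-threshold
#' majorities yield `"ambiguous"`. Strands with no reads are `NA`.
#'
#' @param alleles character vector of per-read allele observations
#'   (`"ref"`, `"alt"`, or anything else treated as other).
#' @param strands character vector (`"top"`/`"bottom"`) parallel to `alleles`.
#' @param majority required consensus fraction (default 2/3).
#' @return named character vector `c(top = , bottom = )`.
#' @export
consensus_by_strand <- function(alleles, strands, majority = 2 / 3) {
  stopifnot(length(alleles) == length(strands), length(alleles) >= 1L)
  out <- c(top = NA_character_, bottom = NA_character_)
  for (s in c("top", "bottom")) {
    a <- alleles[strands == s]
    if (!length(a)) next
    tab <- sort(table(a), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) {
      out[s] <- "ambiguous"
    } else if (tab[1L] / length(a) >= majority) {
      out[s] <- names(tab)[1L]
    } else {
      out[s] <- "ambiguous"
    }
  }
  out
}

#' Count duplex and single-strand molecules from read bundles
#'
#' A bundle with non-ambiguous consensus on both strands counts as a duplex
#' molecule of the consensus allele when both strands agree (alt -> duplex
#' alternate, ref -> duplex wild-type); with consensus on exactly one strand
#' it counts as a single-strand molecule of that allele. Bundles with
#' conflicting strand consensuses or no usable consensus are dropped as
#' ambiguous; bundles whose probe is not in `targets` are tallied off-target.
#'
#' @param grouped output of [group_read_bundles()].
#' @param targets optional character vector of target probe ids (default: all
#'   probes seen).
#' @param majority consensus threshold passed to [consensus_by_strand()].
#' @return molecule-count table (one row per probe x sample with columns
#'   `duplex_alt, single_strand_alt, duplex_wt, single_strand_wt, total_alt,
#'   total_wt`), with `ambiguous` and `off_target` bundle tallies as
#'   attributes.
#' @export
count_molecules <- function(grouped, targets = NULL, majority = 2 / 3) {
  reads <- grouped$reads
  bundles <- grouped$bundles
  if (is.null(targets)) targets <- unique(bundles$probe_id)

  cons <- t(vapply(split(seq_len(nrow(reads)), reads$bundle_id),
                   function(idx) {
                     consensus_by_strand(reads$base_at_target[idx],
                                         reads$strand[idx], majority)
                   }, character(2)))
  cons <- cons[match(bundles$bundle_id, rownames(cons)), , drop = FALSE]

  usable <- function(x) !is.na(x) & x %in% c("ref", "alt")
  top_ok <- usable(cons[, "top"])
  bot_ok <- usable(cons[, "bottom"])
  n_ok <- top_ok + bot_ok
  allele_one <- ifelse(top_ok, cons[, "top"], cons[, "bottom"])

  status <- rep("ambiguous", nrow(bundles))
  status[n_ok == 2L & cons[, "top"] == cons[, "bottom"]] <- "duplex"
  status[n_ok == 1L] <- "single_strand"
  off <- !(bundles$probe_id %in% targets)
  status[off] <- "off_target"

  allele <- ifelse(status == "duplex", cons[, "top"],
                   ifelse(status == "single_strand", allele_one, NA))

  keys <- unique(bundles[bundles$probe_id %in% targets,
                         c("probe_id", "sample_id")])
  tally <- function(st, al) {
    idx <- which(status == st & allele == al)
    if (!length(idx)) return(integer(nrow(keys)))
    tab <- table(factor(paste(bundles$probe_id[idx], bundles$sample_id[idx],
                              sep = "\r"),
                        levels = paste(keys$probe_id, keys$sample_id,
                                       sep = "\r")))
    as.integer(tab)
  }
  out <- data.frame(
    probe_id = keys$probe_id,
    sample_id = keys$sample_id,
    duplex_alt = tally("duplex", "alt"),
    single_strand_alt = tally("single_strand", "alt"),
    duplex_wt = tally("duplex", "ref"),
    single_strand_wt = tally("single_strand", "ref"),
    stringsAsFactors = FALSE)
  out$total_alt <- out$duplex_alt + out$single_strand_alt
  out$total_wt <- out$duplex_wt + out$single_strand_wt
  out <- out[order(out$sample_id, out$probe_id), ]
  rownames(out) <- NULL
  attr(out, "ambiguous") <- sum(status == "ambiguous")
  attr(out, "off_target") <- sum(status == "off_target")
  out
}
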