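#' Group reads into UMI families with consensus calling
#'
#' Reads sharing a UMI form a family; the family gets a consensus sequence only
#' when the modal read sequence accounts for at least `consensus_threshold`
#' (default 70%) of the family, otherwise the family is flagged ambiguous
#' (`consensus` is `NA`) and excluded from molecule counting.
#'
#' @param reads Data.frame with columns `umi` and `sequence` (one row per read).
#' @param consensus_threshold Minimum modal-sequence fraction, default 0.7.
#' @return Data.frame with one row per distinct UMI: `umi`, `read_count`,
#'   `consensus` (`NA_character_` when below threshold).
#' @export
group_by_umi <- function(reads, consensus_threshold = 0.7) {
  stopifnot(is.data.frame(reads), all(c("umi", "sequence") %in% names(reads)))
  if (nrow(reads) == 0L) {
    return(data.frame(umi = character(), read_count = integer(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  if (length(unique(nchar(reads$umi))) != 1L) {
    stop("mixed UMI lengths")
  }
  fam <- split(reads$sequence, reads$umi)
  umi <- names(fam)
  read_count <- lengths(fam)
  consensus <- vapply(fam, function(seqs) {
    tab <- sort(table(seqs), decreasing = TRUE)
    # deterministic modal choice: largest count, then lexicographic
    top <- names(tab)[tab == tab[1L]]
    modal <- sort(top)[1L]
    if (tab[[1L]] / length(seqs) >= consensus_threshold) modal else NA_character_
  }, character(1L))
  res <- data.frame(umi = umi, read_count = as.integer(read_count),
                    consensus = unname(consensus), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$umi), , drop = FALSE]
}

#' Pairwise Hamming distances between equal-length strings
#'
#' @param x Character vector of equal-length strings.
#' @return Integer matrix of pairwise Hamming distances.
#' @export
hamming_matrix <- function(x) {
  if (length(unique(nchar(x))) > 1L) stop("strings must have equal length")
  n <- length(x)
  D <- matrix(0L, n, n, dimnames = list(x, x))
  if (n < 2L) return(D)
  m <- do.call(rbind, strsplit(x, ""))
  for (j in seq_len(ncol(m))) {
    D <- D + outer(m[, j], m[, j], `!=`)
  }
  storage.mode(D) <- "integer"
  dimnames(D) <- list(x, x)
  D
}

#' Cluster UMI families by Hamming-distance graph merging
#'
#' Builds a graph with an edge between any two UMIs at Hamming distance at most
#' `max_dist` (default 2); connected components are merged into one molecule
#' each, retaining the UMI with the highest read count (ties broken
#' lexicographically). This guards against over-counting molecules whose UMIs
#' differ only by sequencing errors.
#'
#' @param families Data.frame from [group_by_umi()]; rows with `NA` consensus
#'   are dropped before clustering.
#' @param max_dist Maximum Hamming distance merged into one cluster, default 2.
#' @return Data.frame with one row per cluster (= unique molecule):
#'   `retained_umi`, `merged_umis` (comma-joined, sorted), `n_umis`,
#'   `total_count`.
#' @export
cluster_umis <- function(families, max_dist = 2L) {
  stopifnot(is.data.frame(families), all(c("umi", "read_count") %in% names(families)))
  if ("consensus" %in% names(families)) {
    families <- families[!is.na(families$consensus), , drop = FALSE]
  }
  if (nrow(families) == 0L) {
    return(data.frame(retained_umi = character(), merged_umis = character(),
                      n_umis = integer(), total_count = integer(),
                      stringsAsFactors = FALSE))
  }
  D <- hamming_matrix(families$umi)
  adj <- D <= max_dist
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  res <- do.call(rbind, lapply(split(seq_len(nrow(families)), comp), function(idx) {
    sub <- families[idx, , drop = FALSE]
    o <- order(-sub$read_count, sub$umi)
    data.frame(retained_umi = sub$umi[o[1L]],
               merged_umis = paste(sort(sub$umi), collapse = ","),
               n_umis = nrow(sub),
               total_count = sum(sub$read_count),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$retained_umi), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Coefficient of variation of per-position molecule counts
#'
#' Standard deviation divided by mean, using the population standard deviation
#' (divisor n). Used as the amplification-uniformity statistic for comparing
#' UMI-barcoded against non-barcoded libraries.
#'
#' @param counts Numeric vector of non-negative counts (>= 2 positions).
#' @return Non-negative real; 0 when all counts are equal.
#' @export
coefficient_of_variation <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need counts for at least two positions")
  if (any(counts < 0)) stop("counts must be non-negative")
  mu <- mean(counts)
  if (mu == 0) stop("mean count is zero; CV undefined")
  sqrt(mean((counts - mu)^2)) / mu
}

#' Primer-match read prefilter
#'
#' Keeps reads whose prefix matches the amplification primer at or above an
#' identity threshold (fraction of matching bases over the primer length,
#' default 0.5). Reads shorter than the primer fail.
#'
#' @param reads Data.frame with a `sequence` column.
#' @param primer Primer sequence expected at the read 5' end.
#' @param min_identity Minimum prefix identity, default 0.5.
#' @return The filtered data.frame.
#' @export
primer_match_filter <- function(reads, primer, min_identity = 0.5) {
  stopifnot(is.data.frame(reads), "sequence" %in% names(reads))
  pl <- nchar(primer)
  pchars <- strsplit(toupper(primer), "")[[1L]]
  keep <- vapply(reads$sequence, function(s) {
    if (nchar(s) < pl) return(FALSE)
    mean(strsplit(toupper(substr(s, 1L, pl)), "")[[1L]] == pchars) >= min_identity
  }, logical(1L), USE.NAMES = FALSE)
  reads[keep, , drop = FALSE]
}
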