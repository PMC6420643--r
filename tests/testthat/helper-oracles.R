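# Independent brute-force oracles used across the suite. These are written as
# plainly as possible (nested loops, exhaustive enumeration) so they share no
# code path with the implementations they check.

# naive O(L * 20) sliding-window protospacer scan, one strand
naive_scan_strand <- function(seq, id, strand, min_window_c, orig_len = nchar(seq)) {
  out <- list()
  L <- nchar(seq)
  if (L >= 23) {
    for (i in 1:(L - 22)) {
      spacer <- substr(seq, i, i + 19)
      pam <- substr(seq, i + 20, i + 22)
      if (substr(pam, 2, 2) != "G" || substr(pam, 3, 3) != "G") next
      if (grepl("N", spacer) || grepl("N", pam)) next
      wpos <- integer()
      for (p in 4:8) if (substr(spacer, p, p) == "C") wpos <- c(wpos, p)
      if (length(wpos) < min_window_c) next
      start <- if (strand == "+") i - 1L else orig_len - (i - 1L) - 20L
      out[[length(out) + 1]] <- data.frame(
        sequence_id = id, start = start, strand = strand,
        spacer = spacer, pam = pam, wpos = paste(wpos, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

naive_scan <- function(seqs, min_window_c = 1) {
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    out[[length(out) + 1]] <- naive_scan_strand(s, id, "+", min_window_c)
    out[[length(out) + 1]] <- naive_scan_strand(rev_comp(s), id, "-", min_window_c,
                                               orig_len = nchar(s))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(res)
  res[order(res$sequence_id, res$start, res$strand), , drop = FALSE]
}

# transitive closure over the exact pairwise Hamming distance matrix
oracle_umi_components <- function(umis, max_dist = 2) {
  n <- length(umis)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- sum(strsplit(umis[i], "")[[1]] != strsplit(umis[j], "")[[1]])
      adj[i, j] <- d <= max_dist
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  # component label = smallest reachable index
  apply(reach, 1, function(r) min(which(r)))
}

# exhaustive 2^n enumeration of the Poisson-binomial CDF
oracle_pb_cdf <- function(probs, k) {
  n <- length(probs)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) <= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# grid-search maximum likelihood for the two-component binomial mixture
oracle_grid_ml <- function(k, n, pis, thetas, epss) {
  best <- NULL
  for (p in pis) for (th in thetas) for (e in epss) {
    ll <- sum(log(p * dbinom(k, n, th) + (1 - p) * dbinom(k, n, e)))
    if (is.null(best) || ll > best$ll) best <- list(pi = p, theta = th, eps = e, ll = ll)
  }
  best
}

# noiseless lineage fixture: every division hands each daughter `k` edits at
# brand-new sites, so the tree is perfectly identifiable
make_perfect_tree <- function(G, k = 2L) {
  n <- 2^(G + 1) - 1
  edits <- list(character())
  nxt <- 0L
  for (i in 2:n) {
    new <- paste0("e", nxt + seq_len(k))
    nxt <- nxt + k
    edits[[i]] <- c(edits[[i %/% 2]], new)
  }
  names(edits) <- paste0("n", seq_len(n))
  truth <- setNames(c(NA_character_, paste0("n", (2:n) %/% 2)), names(edits))
  list(barcodes = edits, truth = truth)
}

# cophenetic distances recomputed from first principles off the merge matrix
oracle_cophenetic <- function(hc) {
  n <- length(hc$labels)
  members <- lapply(seq_len(n), identity)   # leaves per merge node
  coph <- matrix(NA_real_, n, n, dimnames = list(hc$labels, hc$labels))
  clusters <- lapply(-seq_len(n), identity)
  get_leaves <- function(idx) {
    if (idx < 0) return(-idx)
    merged[[idx]]
  }
  merged <- list()
  for (m in seq_len(nrow(hc$merge))) {
    a <- get_leaves(hc$merge[m, 1])
    b <- get_leaves(hc$merge[m, 2])
    for (i in a) for (j in b) coph[i, j] <- coph[j, i] <- hc$height[m]
    merged[[m]] <- c(a, b)
  }
  diag(coph) <- 0
  coph
}
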