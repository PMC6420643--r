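#' Build the edit co-occurrence network from node barcodes
#'
#' Vertices are edits; an edit's expressing set is the set of nodes (samples)
#' whose barcode carries it, and two edits are joined by an edge when they are
#' co-observed in at least one node. This substitution graph is the substrate
#' for clade detection and top-node selection in bulk tree reconstruction.
#'
#' @param barcodes Either a logical/0-1 matrix (samples x edits, dimnames
#'   required or generated) or a named list mapping sample id to a character
#'   vector of edit ids.
#' @param depth Optional numeric matrix (samples x edits) of sequencing depths
#'   supporting each (edit, node) observation; used by the legacy depth-weight
#'   clade mode.
#' @return Object of class `edit_network`: list with `inc` (logical incidence
#'   matrix), `samples`, `edits`, `counts` (edit x edit co-observation counts),
#'   `sizes` (expressing-set sizes), `adj` (logical co-observation adjacency),
#'   `depth`.
#' @export
build_edit_network <- function(barcodes, depth = NULL) {
  inc <- .as_incidence(barcodes)
  if (nrow(inc) < 1L) stop("need at least one barcode")
  counts <- crossprod(inc * 1L)            # co-observation counts
  sizes <- diag(counts)
  adj <- counts > 0
  diag(adj) <- FALSE
  structure(list(inc = inc, samples = rownames(inc), edits = colnames(inc),
                 counts = counts, sizes = sizes, adj = adj, depth = depth),
            class = "edit_network")
}

.as_incidence <- function(barcodes) {
  if (is.matrix(barcodes)) {
    inc <- barcodes > 0
    if (is.null(dimnames(inc))) dimnames(inc) <- list(NULL, NULL)
    if (is.null(rownames(inc))) rownames(inc) <- paste0("s", seq_len(nrow(inc)))
    if (is.null(colnames(inc)) && ncol(inc) > 0L) {
      colnames(inc) <- paste0("e", seq_len(ncol(inc)))
    }
    return(inc)
  }
  if (is.list(barcodes)) {
    edits <- sort(unique(unlist(barcodes, use.names = FALSE)))
    inc <- matrix(FALSE, length(barcodes), length(edits),
                  dimnames = list(names(barcodes), edits))
    for (i in seq_along(barcodes)) inc[i, match(barcodes[[i]], edits)] <- TRUE
    return(inc)
  }
  stop("barcodes must be a matrix or a named list of edit-id vectors")
}

#' Partition edits into clades by overlap-thresholded connected components
#'
#' Keeps an edge between two co-observed edits only when the Jaccard overlap of
#' their expressing node-sets is at least `min_overlap`; connected components
#' under the retained edges are the clades. Nodes in the same clade share a
#' much larger fraction of their barcodes than nodes in different clades, so
#' thresholding removes the spurious cross-clade links that plain connected
#' components would follow. With `min_overlap = 0` the partition reduces to
#' plain co-observation components.
#'
#' The package's earlier depth-weight strategy (greedy traversal maximizing the
#' summed sequencing depth of a component) is kept as `legacy_depth = TRUE`; it
#' uses unthresholded edges and only orders the clades by total depth.
#'
#' @param network An `edit_network` from [build_edit_network()].
#' @param min_overlap Minimum expressing-set Jaccard to retain an edge
#'   (default 0.3).
#' @param legacy_depth Use the legacy depth-weight mode instead.
#' @return List of character vectors of edit ids (a partition of the edits),
#'   ordered by decreasing clade size (legacy mode: decreasing total depth).
#' @export
find_clades <- function(network, min_overlap = 0.3, legacy_depth = FALSE) {
  stopifnot(inherits(network, "edit_network"))
  counts <- network$counts
  sizes <- network$sizes
  if (legacy_depth) {
    adj <- network$adj
  } else {
    un <- outer(sizes, sizes, `+`) - counts
    jac <- ifelse(un > 0, counts / un, 0)
    adj <- network$adj & jac >= min_overlap
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  clades <- split(network$edits, memb)
  wt <- if (legacy_depth && !is.null(network$depth)) {
    vapply(clades, function(e) sum(network$depth[, e, drop = FALSE]), numeric(1L))
  } else {
    lengths(clades)
  }
  clades <- clades[order(-wt, vapply(clades, `[`, character(1L), 1L))]
  names(clades) <- NULL
  lapply(clades, unname)
}

#' Detection rate of an edit
#'
#' Assuming edit `x` is a top (ancestral) edit of its clade, its detection rate
#' is p(x) = N_(x and C(x)) / N_(C(x)): the number of nodes expressing both x
#' and at least one edit connected to x, divided by the number of nodes
#' expressing edits connected to x. A true top edit is carried by (almost) all
#' nodes that carry its descendants, giving p(x) near 1.
#'
#' @param x Edit id.
#' @param network An `edit_network`.
#' @param within Optional character vector restricting the connected-edit set
#'   C(x) to a clade.
#' @return Detection rate in \[0, 1\]. Errors when x has no connected edit.
#' @export
detection_rate <- function(x, network, within = NULL) {
  stopifnot(inherits(network, "edit_network"))
  if (!x %in% network$edits) stop("unknown edit: ", x)
  nbr <- network$edits[network$adj[x, ]]
  if (!is.null(within)) nbr <- intersect(nbr, setdiff(within, x))
  if (length(nbr) == 0L) stop("edit ", x, " has no connected edit; detection rate undefined")
  expressing_nbr <- rowSums(network$inc[, nbr, drop = FALSE]) > 0
  n_c <- sum(expressing_nbr)
  n_xc <- sum(expressing_nbr & network$inc[, x])
  n_xc / n_c
}

#' Chance of observing a connection between two edits in at least one cell
#'
#' p(x - y) = 1 - (1 - p(x))^Ny, where p(x) is the detection rate of x and Ny
#' the number of nodes expressing edit y: the probability that at least one of
#' the Ny nodes carrying y also reveals x.
#'
#' @param p_x Detection rate of edit x, in \[0, 1\].
#' @param n_y Number of nodes expressing edit y (non-negative integer).
#' @return Probability in \[0, 1\].
#' @export
pairwise_edit_probability <- function(p_x, n_y) {
  if (any(p_x < 0 | p_x > 1)) stop("detection rate p_x must lie in [0, 1]")
  if (any(n_y < 0)) stop("expressing-node count n_y must be non-negative")
  1 - (1 - p_x)^n_y
}

#' Poisson-binomial cumulative distribution function
#'
#' P(X <= k) for X a sum of independent Bernoulli trials with individual
#' success probabilities `success_probs`, computed by dynamic-programming
#' convolution (exact to floating precision).
#'
#' @param success_probs Numeric vector of probabilities in \[0, 1\].
#' @param k Integer in 0..length(success_probs).
#' @return P(X <= k).
#' @export
poisson_binomial_cdf <- function(success_probs, k) {
  p <- as.numeric(success_probs)
  if (any(p < 0 | p > 1)) stop("success probabilities must lie in [0, 1]")
  k <- as.integer(k)
  if (k < 0L || k > length(p)) stop("k out of range 0..", length(p))
  dp <- c(1, numeric(length(p)))       # dp[j + 1] = P(X = j)
  for (pi in p) {
    dp <- dp * (1 - pi) + c(0, dp[-length(dp)]) * pi
  }
  sum(dp[seq_len(k + 1L)])
}

#' Select the top (ancestral) edit of a clade
#'
#' For each candidate edit x the potential connections are all other clade
#' members y, each reachable with probability p(x - y) =
#' [pairwise_edit_probability()] built from x's detection rate; the observed
#' degree is the number of clade members actually co-observed with x. The
#' candidate's score is the Poisson-binomial probability of seeing at most the
#' observed degree, and the edit with the highest score is the top node (an
#' ancestral edit is expected to realize all its potential connections). Ties
#' break toward the larger expressing set, then lexicographic edit id.
#'
#' @param clade_edits Character vector of edit ids forming one clade.
#' @param network An `edit_network`.
#' @return The selected edit id.
#' @export
select_top_node <- function(clade_edits, network) {
  stopifnot(inherits(network, "edit_network"))
  if (length(clade_edits) == 0L) stop("empty clade")
  if (length(clade_edits) == 1L) return(clade_edits)
  sizes <- network$sizes
  score <- vapply(clade_edits, function(x) {
    others <- setdiff(clade_edits, x)
    observed <- sum(network$adj[x, others])
    if (observed == 0L) return(-Inf)
    p_x <- detection_rate(x, network, within = clade_edits)
    probs <- pairwise_edit_probability(p_x, sizes[others])
    poisson_binomial_cdf(probs, observed)
  }, numeric(1L))
  if (all(!is.finite(score))) {  # no candidate with a connection: fall back
    o <- order(-sizes[clade_edits], clade_edits)
    return(clade_edits[o[1L]])
  }
  o <- order(-score, -sizes[clade_edits], clade_edits)
  clade_edits[o[1L]]
}

#' Reconstruct a bulk lineage tree from node barcodes
#'
#' Implements the iterative graph reconstruction: the first ancestor node is
#' identified and removed (an unedited founder -- empty barcode -- when
#' present, otherwise the sample with maximal degree in the barcode-sharing
#' graph, ties broken by fewest edits); the remaining nodes' edits form a
#' substitution graph partitioned into clades by overlap-thresholded connected
#' components ([find_clades()]); within each clade the top edit is selected by
#' Poisson-binomial scoring ([select_top_node()]), detached, and the procedure
#' recurses on the remaining components, assembling parent links between
#' detached tops. Samples are then placed at the edit whose ancestor chain
#' best matches their barcode (maximal Jaccard overlap), and sample
#' parent-child links are read off the placement: a node's parent is the
#' nearest placed node up its edit chain (nodes sharing an edit are ordered by
#' barcode size, ancestors carrying fewer edits).
#'
#' @param barcodes Samples-x-edits logical/0-1 matrix (dimnames used as ids)
#'   or named list of edit-id vectors, as for [build_edit_network()].
#' @param min_overlap Jaccard threshold for clade edges, default 0.3.
#' @return Object of class `edit_tree`: list with `samples`, `root`,
#'   `sample_parent` (named character, `NA` at the root), `sample_depth`,
#'   `placed_edit` (named character, `NA` for samples at the virtual root),
#'   `edit_parent` (named character over edits, `NA` for clade roots), and
#'   `min_overlap`.
#' @export
reconstruct_tree <- function(barcodes, min_overlap = 0.3) {
  inc <- .as_incidence(barcodes)
  if (nrow(inc) < 2L) stop("need at least 2 barcodes")
  samples <- rownames(inc)
  edits <- colnames(inc)
  active <- colSums(inc) > 0
  if (!any(active)) {
    # no edits anywhere: degenerate single-root tree
    root <- samples[1L]
    parent <- setNames(rep(root, length(samples)), samples)
    parent[root] <- NA_character_
    return(.new_edit_tree(samples, root, parent,
                          placed = setNames(rep(NA_character_, length(samples)), samples),
                          edit_parent = setNames(rep(NA_character_, length(edits)), edits),
                          min_overlap = min_overlap))
  }
  sub <- inc[, active, drop = FALSE]
  tie_rank <- as.integer(rank(colnames(sub), ties.method = "first"))
  res <- recon_core(sub, min_overlap, tie_rank)
  decode <- function(idx, labels) {
    out <- rep(NA_character_, length(idx))
    out[idx >= 0L] <- labels[idx[idx >= 0L] + 1L]
    out
  }
  root <- samples[res$root + 1L]
  sp <- setNames(decode(res$sample_parent, samples), samples)
  placed <- setNames(decode(res$placed, colnames(sub)), samples)
  ep <- setNames(rep(NA_character_, length(edits)), edits)
  ep[colnames(sub)] <- decode(res$edit_parent, colnames(sub))
  .new_edit_tree(samples, root, sp, placed, ep, min_overlap)
}

.new_edit_tree <- function(samples, root, parent, placed, edit_parent, min_overlap) {
  structure(list(samples = samples, root = root, sample_parent = parent,
                 sample_depth = tree_depths(parent), placed_edit = placed,
                 edit_parent = edit_parent, min_overlap = min_overlap),
            class = "edit_tree")
}

#' Depths of nodes given a parent map
#'
#' @param parent Named character vector mapping node to parent (`NA` at roots).
#' @return Named integer vector of depths (root = 0).
#' @export
tree_depths <- function(parent) {
  nodes <- names(parent)
  pi <- match(parent, nodes)
  depth <- rep(NA_integer_, length(nodes))
  depth[is.na(pi)] <- 0L
  remaining <- which(is.na(depth))
  while (length(remaining)) {
    ready <- remaining[!is.na(depth[pi[remaining]])]
    if (length(ready) == 0L) stop("cycle in parent map")
    depth[ready] <- depth[pi[ready]] + 1L
    remaining <- setdiff(remaining, ready)
  }
  setNames(depth, nodes)
}

#' @export
print.edit_tree <- function(x, ...) {
  cat(sprintf("Reconstructed lineage tree: %d samples, root = %s, max depth = %d\n",
              length(x$samples), x$root, max(x$sample_depth)))
  invisible(x)
}

#' Placement accuracy of a reconstructed tree against the truth
#'
#' A node is placed correctly when both its parent and its depth match the
#' known tree; accuracy is the fraction of correctly placed nodes.
#'
#' @param reconstructed An `edit_tree` (or named parent vector, `NA` at root).
#' @param truth The known tree in the same form, over the same samples.
#' @return List with `correct`, `total`, `accuracy`.
#' @export
placement_accuracy <- function(reconstructed, truth) {
  rp <- if (inherits(reconstructed, "edit_tree")) reconstructed$sample_parent else reconstructed
  tp <- if (inherits(truth, "edit_tree")) truth$sample_parent else truth
  if (!setequal(names(rp), names(tp))) stop("sample sets differ between trees")
  rp <- rp[names(tp)]
  rd <- tree_depths(rp)
  td <- tree_depths(tp)
  same_parent <- (is.na(rp) & is.na(tp)) | (!is.na(rp) & !is.na(tp) & rp == tp)
  ok <- same_parent & rd == td
  list(correct = sum(ok), total = length(ok), accuracy = mean(ok))
}

#' Write a sample lineage tree as Newick
#'
#' Serializes the sample parent map of an [reconstruct_tree()] result (internal
#' samples appear as labelled internal nodes).
#'
#' @param tree An `edit_tree` or named parent vector (`NA` at the root).
#' @param path Optional output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  parent <- if (inherits(tree, "edit_tree")) tree$sample_parent else tree
  kids <- split(names(parent)[!is.na(parent)], parent[!is.na(parent)])
  root <- names(parent)[is.na(parent)]
  if (length(root) != 1L) stop("tree must have exactly one root")
  fmt <- function(v) {
    ch <- kids[[v]]
    if (is.null(ch)) return(v)
    paste0("(", paste(vapply(sort(ch), fmt, character(1L)), collapse = ","), ")", v)
  }
  nwk <- paste0(fmt(root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
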