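#' Jaccard distance matrix between cell barcodes
#'
#' Distance between two cells is 1 - |A intersect B| / |A union B| over their
#' edited-site sets (binary barcode vectors). A pair of cells with no edits at
#' all has an undefined Jaccard index; it is defined here as distance 0 (two
#' unedited cells are indistinguishable). Computation is delegated to
#' `vegan::vegdist(..., method = "jaccard", binary = TRUE)`.
#'
#' @param barcodes Cells-x-sites binary matrix (rownames = cell ids).
#' @param blacklist Optional character vector of site (column) ids removed
#'   before computing distances, e.g. sites seen in marker-negative or
#'   vehicle-control cells.
#' @return Object of class `dist_matrix`: list with `sample_ids` and symmetric
#'   matrix `d` (zero diagonal, values in \[0, 1\]).
#' @export
jaccard_distance_matrix <- function(barcodes, blacklist = character()) {
  m <- as.matrix(barcodes) > 0
  if (nrow(m) < 2L) stop("need at least 2 cells")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (length(blacklist)) m <- m[, !(colnames(m) %in% blacklist), drop = FALSE]
  if (ncol(m) == 0L) {
    d <- matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  } else {
    dd <- suppressWarnings(vegan::vegdist(m * 1, method = "jaccard", binary = TRUE))
    d <- as.matrix(dd)
    d[is.nan(d)] <- 0   # both-empty pairs: defined as distance 0
    diag(d) <- 0
  }
  structure(list(sample_ids = rownames(m), d = d), class = "dist_matrix")
}

.as_dist_obj <- function(d) {
  if (inherits(d, "dist_matrix")) return(d)
  m <- as.matrix(d)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("cell", seq_len(nrow(m)))
  structure(list(sample_ids = rownames(m), d = m), class = "dist_matrix")
}

#' Average-linkage (UPGMA-style) hierarchical clustering of cells
#'
#' Agglomerates cells under average linkage on a precomputed distance matrix
#' via [stats::hclust()]; merge heights are monotone non-decreasing and the
#' tree is deterministic for a given input.
#'
#' @param d A `dist_matrix` from [jaccard_distance_matrix()], a `dist`, or a
#'   symmetric matrix.
#' @return An `hclust` object with cell labels.
#' @export
average_linkage_tree <- function(d) {
  d <- .as_dist_obj(d)
  hclust(as.dist(d$d), method = "average")
}

#' Site-bootstrap support for a cell dendrogram
#'
#' Resamples barcode sites (columns) with replacement `n_boot` times,
#' reclusters each replicate with average linkage on Jaccard distances, and
#' scores every internal node of the reference dendrogram by the fraction of
#' replicates containing the same leaf clade (ordinary Felsenstein bootstrap;
#' clade counting via [ape::prop.clades()]).
#'
#' @param barcodes Cells-x-sites binary matrix.
#' @param n_boot Number of bootstrap replicates, default 1000.
#' @param seed RNG seed for the resampling.
#' @param blacklist Optional site blacklist, as in
#'   [jaccard_distance_matrix()].
#' @return List with `hclust` (reference tree), `phylo` (ape tree whose node
#'   labels are supports in percent), and `support` (fraction in \[0, 1\] per
#'   internal node, in `phylo` node order).
#' @export
bootstrap_support <- function(barcodes, n_boot = 1000L, seed = 1L,
                              blacklist = character()) {
  m <- as.matrix(barcodes) > 0
  if (nrow(m) < 3L) stop("need at least 3 cells")
  if (is.null(rownames(m))) rownames(m) <- paste0("cell", seq_len(nrow(m)))
  if (length(blacklist)) m <- m[, !(colnames(m) %in% blacklist), drop = FALSE]
  ref_hc <- average_linkage_tree(jaccard_distance_matrix(m))
  ref_ph <- ape::as.phylo(ref_hc)
  n_internal <- ref_ph$Nnode
  informative <- ncol(m) > 0L && any(colSums(m) > 0L & colSums(m) < nrow(m))
  if (!informative) {
    support <- rep(0, n_internal)
  } else {
    set.seed(seed)
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      hb <- average_linkage_tree(jaccard_distance_matrix(m[, cols, drop = FALSE]))
      boots[[b]] <- ape::as.phylo(hb)
    }
    cnt <- ape::prop.clades(ref_ph, boots, rooted = TRUE)
    cnt[is.na(cnt)] <- 0
    support <- cnt / n_boot
  }
  ref_ph$node.label <- formatC(round(support * 100), format = "d")
  list(hclust = ref_hc, phylo = ref_ph, support = support)
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the original pairwise distances and the
#' cophenetic distances implied by the dendrogram; 1 means the tree reproduces
#' the distance structure exactly (ultrametric input).
#'
#' @param dendrogram An `hclust` object (or the list from
#'   [bootstrap_support()]).
#' @param d The original distances (`dist_matrix`, `dist`, or matrix) over the
#'   same leaves.
#' @return Correlation in \[-1, 1\]. Errors on constant distances.
#' @export
cophenetic_correlation <- function(dendrogram, d) {
  if (is.list(dendrogram) && !inherits(dendrogram, "hclust") &&
      !is.null(dendrogram$hclust)) {
    dendrogram <- dendrogram$hclust
  }
  d <- .as_dist_obj(d)
  if (!setequal(dendrogram$labels, d$sample_ids)) stop("leaves do not match distances")
  coph <- as.matrix(cophenetic(dendrogram))
  ord <- d$sample_ids
  x <- as.dist(d$d[ord, ord])
  y <- as.dist(coph[ord, ord])
  if (sd(x) == 0 || sd(y) == 0) stop("constant distances; correlation undefined")
  cor(x, y)
}
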