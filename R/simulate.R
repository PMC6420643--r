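#' Simulation parameters for barcode accumulation on a binary lineage tree
#'
#' Defaults encode the study conditions of the targeted-deaminase system: a
#' 30% target-site dropout rate (mimicking loss of target sequence that a
#' nuclease-based system would suffer), 10% of sites biased toward fast
#' saturation with bias parameter `b = 0.9` (biased sites edit at rate
#' `min(1, F / b)`), one generation per simulated day, and full binary growth
#' (generation g holds 2^g cells).
#'
#' @param G Number of generations (tree depth), >= 1.
#' @param N Number of target sites, >= 1.
#' @param F Editing rate in mutations/site/cell division, in (0, 1\] (0 allowed
#'   for degenerate controls).
#' @param dropout_rate Probability that a site is removed from the editable
#'   pool, in \[0, 1); default 0.3.
#' @param bias_fraction Fraction of sites that saturate quickly, default 0.1.
#' @param b Bias parameter (1 - site editing bias) in (0, 1\]; default 0.9.
#' @param seed RNG seed.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(G, N, F, dropout_rate = 0.3, bias_fraction = 0.1,
                       b = 0.9, seed = 1L) {
  stopifnot(G >= 1, N >= 1, F >= 0, F <= 1,
            dropout_rate >= 0, dropout_rate < 1,
            bias_fraction >= 0, bias_fraction <= 1,
            b > 0, b <= 1)
  structure(list(G = as.integer(G), N = as.integer(N), F = F,
                 dropout_rate = dropout_rate, bias_fraction = bias_fraction,
                 b = b, seed = as.integer(seed)),
            class = "sim_params")
}

#' Draw the editable site set under dropout
#'
#' Each of the N sites stays editable independently with probability
#' 1 - dropout_rate (binomial site removal).
#'
#' @param N Number of sites.
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Logical vector of length N, `TRUE` for editable sites.
#' @export
apply_dropout <- function(N, dropout_rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runif(N) <= 1 - dropout_rate
}

#' Simulate barcode accumulation on a full binary lineage tree
#'
#' Starting from an unedited founder, every division copies the mother's edit
#' set to both daughters and then flips each still-unedited editable site with
#' per-division probability F (biased sites: `min(1, F / b)`). Edits are
#' irreversible C>T conversions, so a child's edit set is always a superset of
#' its mother's. Nodes are heap-indexed: node 1 is the founder, node i has
#' daughters 2i and 2i+1, and generation g holds nodes 2^g .. 2^(g+1)-1.
#'
#' The random draws for dropout, bias assignment, and per-division editing have
#' identical shapes regardless of the parameter values, so paired runs that
#' share a seed and differ in one parameter isolate that parameter's effect.
#'
#' @param params A `sim_params` object.
#' @return Object of class `sim_tree`: list with `params`, `barcodes` (logical
#'   matrix, (2^(G+1)-1) x N, row i = node i), `editable`, `biased` (logical
#'   site vectors), `generation` (per node), `parent` (heap parent index,
#'   NA for the founder).
#' @export
simulate_tree <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  N <- params$N; G <- params$G
  editable <- runif(N) <= 1 - params$dropout_rate
  bias_scores <- runif(N)
  n_biased <- round(params$bias_fraction * N)
  biased <- logical(N)
  if (n_biased > 0) biased[order(bias_scores)[seq_len(n_biased)]] <- TRUE
  rate <- ifelse(biased, pmin(1, params$F / params$b), params$F)
  rate[!editable] <- 0
  n_nodes <- 2L^(G + 1L) - 1L
  bc <- matrix(FALSE, n_nodes, N)
  for (g in seq_len(G)) {
    idx <- (2L^g):(2L^(g + 1L) - 1L)
    mother <- bc[idx %/% 2L, , drop = FALSE]
    u <- matrix(runif(length(idx) * N), length(idx), N)
    new_edit <- sweep(u, 2L, rate, `<`) & !mother
    bc[idx, ] <- mother | new_edit
  }
  rownames(bc) <- paste0("n", seq_len(n_nodes))
  colnames(bc) <- paste0("site", seq_len(N))
  gen <- floor(log2(seq_len(n_nodes)))
  parent <- c(NA_integer_, (2L:n_nodes) %/% 2L)
  structure(list(params = params, barcodes = bc, editable = editable,
                 biased = biased, generation = as.integer(gen),
                 parent = parent),
            class = "sim_tree")
}

#' @export
print.sim_tree <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Simulated lineage tree: G = %d (%d nodes), N = %d sites (%d editable), F = %g\n",
    p$G, nrow(x$barcodes), p$N, sum(x$editable), p$F))
  invisible(x)
}

#' True parent map of (a subtree of) a simulated tree
#'
#' @param tree A `sim_tree`.
#' @param generation Truncate to nodes of generations 0..`generation`
#'   (default: full depth).
#' @return Named character parent vector (`NA` at the founder), usable with
#'   [placement_accuracy()] and [triplet_accuracy()].
#' @export
sim_truth_parents <- function(tree, generation = tree$params$G) {
  n <- 2L^(generation + 1L) - 1L
  p <- ifelse(is.na(tree$parent[seq_len(n)]), NA_character_,
              paste0("n", tree$parent[seq_len(n)]))
  setNames(p, paste0("n", seq_len(n)))
}

#' Barcode matrix of a simulated subtree
#'
#' @param tree A `sim_tree`.
#' @param generation Include nodes of generations 0..`generation`.
#' @return Logical matrix (nodes x sites) over sites edited somewhere in the
#'   subtree.
#' @export
sim_subtree_barcodes <- function(tree, generation = tree$params$G) {
  n <- 2L^(generation + 1L) - 1L
  m <- tree$barcodes[seq_len(n), , drop = FALSE]
  m[, colSums(m) > 0, drop = FALSE]
}

#' Triplet accuracy of a reconstructed tree
#'
#' A triplet is a mother together with its two daughters; it is correctly
#' placed when the reconstruction assigns both daughters to that mother.
#' Accuracy is correct triplets over total triplets (a depth-3 tree of
#' 1 + 2 + 4 = 7 cells has 3 triplets).
#'
#' @param truth A `sim_tree`, or a named parent vector (`NA` at the root).
#' @param reconstructed An `edit_tree` from [reconstruct_tree()] or a named
#'   parent vector, over the same node set.
#' @param generation When `truth` is a `sim_tree`, truncate to this depth.
#' @return List with `correct`, `total`, `accuracy`.
#' @export
triplet_accuracy <- function(truth, reconstructed, generation = NULL) {
  tp <- if (inherits(truth, "sim_tree")) {
    sim_truth_parents(truth, if (is.null(generation)) truth$params$G else generation)
  } else truth
  rp <- if (inherits(reconstructed, "edit_tree")) reconstructed$sample_parent else reconstructed
  if (!setequal(names(tp), names(rp))) stop("node sets differ between trees")
  rp <- rp[names(tp)]
  kids <- split(names(tp)[!is.na(tp)], tp[!is.na(tp)])
  kids <- kids[lengths(kids) == 2L]
  if (length(kids) == 0L) stop("truth tree has no mother-with-two-daughters triplet")
  ok <- vapply(names(kids), function(m) {
    d <- kids[[m]]
    !is.na(rp[[d[1L]]]) && !is.na(rp[[d[2L]]]) &&
      rp[[d[1L]]] == m && rp[[d[2L]]] == m
  }, logical(1L))
  list(correct = sum(ok), total = length(ok), accuracy = mean(ok))
}

## Aggregate (union) edit sets of every subtree root down to `depth`.
.clade_aggregates <- function(tree, depth) {
  n <- 2L^(depth + 1L) - 1L
  agg <- tree$barcodes[seq_len(n), , drop = FALSE]
  if (depth >= 1L) {
    for (g in seq(depth - 1L, 0L)) {
      idx <- (2L^g):(2L^(g + 1L) - 1L)
      agg[idx, ] <- agg[idx, , drop = FALSE] |
        agg[2L * idx, , drop = FALSE] | agg[2L * idx + 1L, , drop = FALSE]
    }
  }
  agg
}

#' Mean barcode sharing between sister clades
#'
#' For each pair of sister clades rooted at the given generation (daughter
#' subtrees of one mother), computes the Jaccard overlap of the clades'
#' aggregate edit sets, truncated at tree depth `depth`; returns the mean over
#' pairs. Pairs in which both clades are unedited are skipped.
#'
#' @param tree A `sim_tree`.
#' @param generation Generation of the sister-clade roots (>= 1).
#' @param depth Depth at which clades are truncated (default: full tree).
#' @return Mean Jaccard sharing in \[0, 1\] (`NaN` when no pair is edited).
#' @export
sister_clade_sharing <- function(tree, generation, depth = tree$params$G) {
  stopifnot(generation >= 1L, generation <= depth, depth <= tree$params$G)
  agg <- .clade_aggregates(tree, depth)
  left <- 2L^generation + 2L * (seq_len(2L^(generation - 1L)) - 1L)
  a <- agg[left, , drop = FALSE]
  b <- agg[left + 1L, , drop = FALSE]
  inter <- rowSums(a & b)
  uni <- rowSums(a | b)
  j <- inter[uni > 0] / uni[uni > 0]
  if (length(j) == 0L) return(NaN)
  mean(j)
}

#' Fraction of editable sites consumed per cell
#'
#' The per-cell fraction of editable sites already edited, minimized over the
#' cells of the given generation ("consumed for all analyzed cells").
#'
#' @param tree A `sim_tree`.
#' @param generation Generation to evaluate (0..G).
#' @return Minimum per-cell consumed fraction in \[0, 1\].
#' @export
consumed_fraction <- function(tree, generation) {
  stopifnot(generation >= 0L, generation <= tree$params$G)
  n_ed <- sum(tree$editable)
  if (n_ed == 0L) return(NaN)
  idx <- (2L^generation):(2L^(generation + 1L) - 1L)
  min(rowSums(tree$barcodes[idx, tree$editable, drop = FALSE]) / n_ed)
}

## mean sharing over all sister-clade pairs (generations 1..g) of the depth-g
## subtree, weighted by the number of pairs per generation
.overall_sharing <- function(tree, g) {
  agg <- .clade_aggregates(tree, g)
  js <- numeric(0)
  for (k in seq_len(g)) {
    left <- 2L^k + 2L * (seq_len(2L^(k - 1L)) - 1L)
    a <- agg[left, , drop = FALSE]
    b <- agg[left + 1L, , drop = FALSE]
    inter <- rowSums(a & b)
    uni <- rowSums(a | b)
    js <- c(js, inter[uni > 0] / uni[uni > 0])
  }
  if (length(js) == 0L) return(NaN)
  mean(js)
}

#' Fraction of correctly ordered ancestor-descendant pairs
#'
#' Alternative accuracy metric: over all node pairs that stand in an
#' ancestor-descendant relation in the truth, the fraction whose order the
#' reconstruction preserves (the ancestor is again an ancestor).
#'
#' @param truth,reconstructed Named parent vectors (or `sim_tree` /
#'   `edit_tree`), same node set.
#' @param generation Truncation depth when `truth` is a `sim_tree`.
#' @return Fraction in \[0, 1\].
#' @export
pairwise_order_accuracy <- function(truth, reconstructed, generation = NULL) {
  tp <- if (inherits(truth, "sim_tree")) {
    sim_truth_parents(truth, if (is.null(generation)) truth$params$G else generation)
  } else truth
  rp <- if (inherits(reconstructed, "edit_tree")) reconstructed$sample_parent else reconstructed
  rp <- rp[names(tp)]
  anc_set <- function(p) {
    lapply(setNames(names(p), names(p)), function(v) {
      out <- character(); u <- v
      while (!is.na(p[[u]])) { u <- p[[u]]; out <- c(out, u) }
      out
    })
  }
  ta <- anc_set(tp); ra <- anc_set(rp)
  ok <- 0L; tot <- 0L
  for (v in names(tp)) {
    for (a in ta[[v]]) {
      tot <- tot + 1L
      if (a %in% ra[[v]]) ok <- ok + 1L
    }
  }
  if (tot == 0L) return(NaN)
  ok / tot
}

#' Default reconstructor for simulation sweeps
#'
#' Mirrors the full tree-building pipeline applied to real data: a marker
#' selection step first removes saturated sites (carried by more than 80% of
#' nodes, hence shared by almost every clone and uninformative) and one site
#' of each highly correlated pair (squared correlation of carriage patterns
#' above 0.8), then the graph reconstruction runs on the retained markers.
#' The normalized-probability saturation rule of [filter_sites()] is disabled
#' here because its threshold is calibrated to the site count of a bulk
#' sequencing design, not to an arbitrary simulated matrix.
#'
#' @param m Nodes-x-sites logical barcode matrix.
#' @param min_overlap Clade threshold passed to [reconstruct_tree()].
#' @return An `edit_tree`.
#' @export
sweep_reconstruct <- function(m, min_overlap = 0.3) {
  if (ncol(m) > 1L && nrow(m) >= 2L) {
    keep <- filter_sites(t(m) * 1, corr_threshold = 0.8,
                         saturation_efficiency = 0.8,
                         saturation_probability = Inf)
    if (length(keep) > 0L) m <- m[, keep, drop = FALSE]
  }
  reconstruct_tree(m, min_overlap = min_overlap)
}

#' Sweep simulated reconstruction accuracy over a parameter grid
#'
#' For every grid row and replicate, simulates one tree to depth G and scores
#' the reconstruction of every depth-g subtree (g = 1..G) with the chosen
#' accuracy metric, along with the sister-clade sharing and consumed-site
#' fraction at that generation. Because editing is cumulative and Markovian,
#' the depth-g subtree of one deep simulation is distributed exactly as an
#' independent simulation run to depth g, so one tree per seed serves the whole
#' generation range. Replicate r uses seed `base_seed + r - 1` in every grid
#' row, giving paired arms across rows.
#'
#' @param grid Data.frame with columns among `G`, `N`, `F`, `dropout_rate`,
#'   `bias_fraction`, `b` (missing columns take the [sim_params()] defaults).
#' @param replicates Replicates per grid row (default 20).
#' @param base_seed First replicate seed.
#' @param min_overlap Clade threshold passed to [reconstruct_tree()].
#' @param reconstructor Tree-building callable `function(barcode_matrix)`
#'   returning an object accepted by [triplet_accuracy()]; default wraps
#'   [reconstruct_tree()].
#' @param metric `"triplet"` (default) or `"pairwise"`
#'   ([pairwise_order_accuracy()]).
#' @return Data.frame with one row per (grid row, replicate, generation):
#'   grid columns plus `replicate`, `seed`, `generation`, `accuracy`,
#'   `sharing`, `consumed`.
#' @export
run_sweep <- function(grid, replicates = 20L, base_seed = 1L, min_overlap = 0.3,
                      reconstructor = NULL, metric = c("triplet", "pairwise")) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(grid), all(c("G", "N", "F") %in% names(grid)))
  defaults <- list(dropout_rate = 0.3, bias_fraction = 0.1, b = 0.9)
  for (nm in names(defaults)) if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  if (is.null(reconstructor)) {
    reconstructor <- function(m) sweep_reconstruct(m, min_overlap = min_overlap)
  }
  out <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      seed <- base_seed + r - 1L
      p <- sim_params(G = grid$G[i], N = grid$N[i], F = grid$F[i],
                      dropout_rate = grid$dropout_rate[i],
                      bias_fraction = grid$bias_fraction[i],
                      b = grid$b[i], seed = seed)
      tree <- simulate_tree(p)
      rows <- lapply(seq_len(p$G), function(g) {
        inc <- sim_subtree_barcodes(tree, g)
        recon <- reconstructor(inc)
        acc <- if (metric == "triplet") {
          triplet_accuracy(tree, recon, generation = g)$accuracy
        } else {
          pairwise_order_accuracy(tree, recon, generation = g)
        }
        data.frame(G = p$G, N = p$N, F = p$F,
                   dropout_rate = p$dropout_rate,
                   bias_fraction = p$bias_fraction, b = p$b,
                   replicate = r, seed = seed, generation = g,
                   accuracy = acc,
                   sharing = .overall_sharing(tree, g),
                   consumed = consumed_fraction(tree, g))
      })
      k <- k + 1L
      out[[k]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
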