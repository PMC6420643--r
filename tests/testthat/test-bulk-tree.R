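test_that("edit network edges equal brute-force co-occurrence enumeration", {
  set.seed(31)
  for (rep in 1:4) {
    n_nodes <- 12; n_edits <- 15
    inc <- matrix(runif(n_nodes * n_edits) < 0.25, n_nodes, n_edits,
                  dimnames = list(paste0("s", 1:n_nodes), paste0("e", 1:n_edits)))
    net <- build_edit_network(inc)
    for (i in 1:n_edits) for (j in 1:n_edits) {
      expected <- i != j && any(inc[, i] & inc[, j])
      expect_identical(unname(net$adj[i, j]), expected)
    }
    expect_true(all(net$sizes == colSums(inc)))
  }
})

test_that("disjoint and shared barcodes give the expected network structure", {
  net <- build_edit_network(list(a = c("x", "y"), b = c("x", "z"), c = "w"))
  expect_true(net$adj["x", "y"] && net$adj["x", "z"])
  expect_false(net$adj["y", "z"])   # never co-observed
  expect_false(any(net$adj["w", ])) # disjoint barcode contributes no edges
})

test_that("clade finding thresholds edges by expressing-set Jaccard", {
  # 4 planted clades: each clade's edits expressed by its own 5 nodes, plus a
  # touch of cross-clade noise that the 0.3 threshold must ignore
  set.seed(17)
  nodes <- paste0("s", 1:20)
  clade_of_node <- rep(1:4, each = 5)
  edits <- paste0("e", 1:24)
  clade_of_edit <- rep(1:4, each = 6)
  inc <- matrix(FALSE, 20, 24, dimnames = list(nodes, edits))
  for (j in 1:24) {
    own <- which(clade_of_node == clade_of_edit[j])
    inc[own, j] <- runif(5) < 0.9
    other <- which(clade_of_node != clade_of_edit[j])
    inc[sample(other, 1), j] <- runif(1) < 0.2
  }
  net <- build_edit_network(inc)
  clades <- find_clades(net, min_overlap = 0.3)
  big <- clades[lengths(clades) > 1]
  expect_equal(length(big), 4L)
  got <- lapply(big, function(cl) sort(unique(clade_of_edit[match(cl, edits)])))
  expect_true(all(lengths(got) == 1L))
})

test_that("min_overlap 0 reduces to plain connected components", {
  inc <- matrix(c(1, 1, 0, 0,
                  0, 1, 1, 0,
                  0, 0, 0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("s", 1:3), paste0("e", 1:4)))
  net <- build_edit_network(inc)
  cl0 <- find_clades(net, min_overlap = 0)
  expect_equal(sort(lengths(cl0), decreasing = TRUE), c(3L, 1L))
  # fully shared edits collapse to one clade
  full <- build_edit_network(matrix(TRUE, 3, 5,
                                    dimnames = list(paste0("s", 1:3), paste0("e", 1:5))))
  expect_equal(length(find_clades(full, min_overlap = 0.3)), 1L)
})

test_that("detection rate counts co-expression per the defining ratio", {
  # neighbors of x expressed by 4 nodes, 3 of which also express x
  inc <- matrix(FALSE, 5, 3, dimnames = list(paste0("s", 1:5), c("x", "y", "z")))
  inc[1:4, "y"] <- TRUE
  inc[1:3, "x"] <- TRUE
  inc[1, "z"] <- TRUE
  net <- build_edit_network(inc)
  expect_equal(detection_rate("x", net), 3 / 4)
  # x co-expressed in every neighbor-expressing node
  inc2 <- matrix(c(1, 1, 1, 1, 1, 0), nrow = 3, byrow = FALSE,
                 dimnames = list(paste0("s", 1:3), c("x", "y")))
  expect_equal(detection_rate("x", build_edit_network(inc2)), 1.0)
  # isolated edit has no defined detection rate
  iso <- build_edit_network(list(a = "x", b = "y"))
  expect_error(detection_rate("x", iso), "no connected edit")
})

test_that("pairwise edit probability follows 1 - (1 - p)^n", {
  expect_equal(pairwise_edit_probability(0, 5), 0)
  expect_equal(pairwise_edit_probability(1, 3), 1)
  expect_equal(pairwise_edit_probability(0.5, 2), 0.75)
  expect_equal(pairwise_edit_probability(0.3, 0), 0)
  expect_error(pairwise_edit_probability(1.2, 1), "in")
})

test_that("Poisson-binomial CDF is exact against exhaustive enumeration", {
  expect_equal(poisson_binomial_cdf(c(0.5, 0.5), 1), 0.75)
  expect_equal(poisson_binomial_cdf(rep(0, 4), 0), 1.0)
  # equal probabilities reduce to the binomial CDF
  expect_equal(poisson_binomial_cdf(rep(0.3, 9), 4), pbinom(4, 9, 0.3))
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(3:12, 1)
    p <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(poisson_binomial_cdf(p, k), oracle_pb_cdf(p, k), tolerance = 1e-12)
  }
  expect_error(poisson_binomial_cdf(c(0.5, 0.5), 3), "out of range")
})

test_that("top-node score is the CDF at the observed degree (4 potential, 3 observed)", {
  # clade {x, a, b, c, d}: x co-observed with a, b, c but not d, and one
  # a-expressing node lacks x so the detection rate is below 1
  nodes <- paste0("s", 1:8)
  inc <- matrix(FALSE, 8, 5, dimnames = list(nodes, c("x", "a", "b", "c", "d")))
  inc[1:5, "x"] <- TRUE
  inc[c(1:2, 6), "a"] <- TRUE
  inc[2:3, "b"] <- TRUE
  inc[4:5, "c"] <- TRUE
  inc[6:8, "d"] <- TRUE
  net <- build_edit_network(inc)
  clade <- c("x", "a", "b", "c", "d")
  p_x <- detection_rate("x", net, within = clade)
  expect_equal(p_x, 5 / 6)
  probs <- pairwise_edit_probability(p_x, net$sizes[c("a", "b", "c", "d")])
  score_x <- poisson_binomial_cdf(probs, 3)   # observed degree 3 of 4 potential
  expect_lt(score_x, 1)
  expect_gt(score_x, 0)
  expect_equal(score_x, oracle_pb_cdf(probs, 3), tolerance = 1e-12)
  expect_equal(select_top_node("a", net), "a")  # singleton clade
})

test_that("top-node selection recovers the earliest edit of noiseless clades", {
  hits <- 0; total <- 0
  left_nodes <- list(`2` = c("n2", "n4", "n5"),
                     `3` = c("n2", "n4", "n5", "n8", "n9", "n10", "n11"))
  for (G in 2:3) {
    for (k in 1:5) {
      pf <- make_perfect_tree(G, k = k)
      edits <- sort(unique(unlist(pf$barcodes)))
      inc <- matrix(FALSE, length(pf$barcodes), length(edits),
                    dimnames = list(names(pf$barcodes), edits))
      for (i in seq_along(pf$barcodes)) inc[i, pf$barcodes[[i]]] <- TRUE
      # left clade = edits of n2's subtree; the earliest are n2's own
      left <- sort(unique(unlist(pf$barcodes[left_nodes[[as.character(G)]]])))
      net <- build_edit_network(inc[-1, , drop = FALSE])  # founder removed
      top <- select_top_node(left, net)
      total <- total + 1
      if (top %in% pf$barcodes[["n2"]]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("noiseless trees are reconstructed exactly at depths 2 to 5", {
  for (G in 2:5) {
    pf <- make_perfect_tree(G)
    tr <- reconstruct_tree(pf$barcodes)
    expect_equal(placement_accuracy(tr, pf$truth)$accuracy, 1.0)
    expect_equal(triplet_accuracy(pf$truth, tr)$accuracy, 1.0)
  }
})

test_that("reconstruction is invariant to barcode input order", {
  pf <- make_perfect_tree(3)
  t1 <- reconstruct_tree(pf$barcodes)
  perm <- sample(seq_along(pf$barcodes))
  t2 <- reconstruct_tree(pf$barcodes[perm])
  expect_equal(t1$sample_parent[sort(names(t1$sample_parent))],
               t2$sample_parent[sort(names(t2$sample_parent))])
})

test_that("a daughter that fully absorbs the wrong mother's barcode is misplaced", {
  # the documented failure mode: chance extra overlap with the wrong mother
  barcodes <- list(
    root = character(),
    m1 = c("a", "b"), m2 = c("c", "d"),
    d1 = c("a", "c", "d", "e"),       # true child of m1, lost b, gained all of m2
    d2 = c("c", "d", "f"),
    d3 = c("a", "b", "g"))
  tr <- reconstruct_tree(barcodes)
  expect_equal(unname(tr$sample_parent[["d1"]]), "m2")
  expect_equal(unname(tr$sample_parent[["d3"]]), "m1")
})

test_that("placement accuracy counts matching parent and depth", {
  pf <- make_perfect_tree(4)
  tr <- reconstruct_tree(pf$barcodes)
  expect_equal(placement_accuracy(tr, pf$truth)$accuracy, 1.0)
  # perturb one node's parent to another node at the same depth: 30/31 correct
  wrong <- pf$truth
  wrong["n31"] <- "n14"   # true parent is n15
  pa <- placement_accuracy(wrong, pf$truth)
  expect_equal(pa$correct, 30L)
  expect_equal(pa$total, 31L)
  expect_equal(round(pa$accuracy, 3), 0.968)
  # star truth against chain reconstruction: only the root and first node agree
  star <- setNames(c(NA, rep("r", 4)), c("r", paste0("x", 1:4)))
  chain <- setNames(c(NA, "r", paste0("x", 1:3)), c("r", paste0("x", 1:4)))
  expect_equal(placement_accuracy(chain, star)$correct, 2L)
  expect_error(placement_accuracy(chain[-1], star), "sample sets differ")
})

test_that("the 35-of-36 arithmetic gives 97%", {
  expect_equal(round(35 / 36, 2), 0.97)
  pa <- list(correct = 35, total = 36, accuracy = 35 / 36)
  expect_equal(round(pa$accuracy, 3), 0.972)
})

test_that("degenerate inputs give a single-root tree", {
  empty <- list(a = character(), b = character(), c = character())
  tr <- reconstruct_tree(empty)
  expect_equal(tr$root, "a")
  expect_true(all(tr$sample_parent[c("b", "c")] == "a"))
  expect_error(reconstruct_tree(list(a = "x")), "at least 2")
})

test_that("sample trees serialize to labelled Newick", {
  pf <- make_perfect_tree(2)
  tr <- reconstruct_tree(pf$barcodes)
  nwk <- write_tree_newick(tr)
  expect_match(nwk, "^\\(.*\\)n1;$")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(c(ph$tip.label, ph$node.label), names(pf$truth))
})
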