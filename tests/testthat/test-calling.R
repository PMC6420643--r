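make_fit <- function(pi, theta, epsilon, ploidy = FALSE) {
  structure(list(pi = pi, theta = theta, epsilon = epsilon, loglik = 0,
                 n_iter = 1L, converged = TRUE, degenerate = FALSE,
                 ploidy_mode = ploidy), class = "mixture_fit")
}

sim_counts <- function(n_sites, depth, pi, theta, eps, seed) {
  set.seed(seed)
  edited <- runif(n_sites) < pi
  d <- rpois(n_sites, depth)
  k <- rbinom(n_sites, d, ifelse(edited, theta, eps))
  data.frame(site_id = paste0("s", seq_len(n_sites)), sample_id = "a",
             depth = d, alt_count = k)
}

test_that("EM fit agrees with a grid-search maximum-likelihood oracle", {
  counts <- sim_counts(120, 80, pi = 0.25, theta = 0.5, eps = 0.003, seed = 5)
  fit <- fit_mixture(counts)
  grid <- oracle_grid_ml(counts$alt_count, counts$depth,
                         pis = seq(0.05, 0.6, by = 0.05),
                         thetas = seq(0.3, 0.7, by = 0.05),
                         epss = c(0.001, 0.003, 0.01, 0.03))
  expect_gte(fit$loglik, grid$ll - 1e-6)   # EM at least matches the grid optimum
  expect_lt(abs(fit$pi - grid$pi), 0.06)
  expect_lt(abs(fit$theta - grid$theta), 0.06)
})

test_that("degenerate and nested-model behavior of the mixture", {
  zero <- data.frame(depth = rep(100L, 20), alt_count = 0L)
  fz <- fit_mixture(zero)
  expect_lte(fz$pi, 0.01)
  expect_true(fz$degenerate)
  # single-component data: 2-component loglik >= 1-component loglik
  set.seed(3)
  d <- rpois(50, 100)
  k <- rbinom(50, d, 0.004)
  f2 <- fit_mixture(data.frame(depth = d, alt_count = k))
  ll1 <- sum(dbinom(k, d, sum(k) / sum(d), log = TRUE))
  expect_gte(f2$loglik, ll1 - 1e-6)
  expect_error(fit_mixture(data.frame(depth = rep(0L, 20), alt_count = 0L)),
               "depth > 0")
})

test_that("fit is invariant to site order", {
  counts <- sim_counts(100, 100, 0.3, 0.5, 0.002, seed = 9)
  f1 <- fit_mixture(counts)
  f2 <- fit_mixture(counts[rev(seq_len(nrow(counts))), ])
  expect_equal(f1$pi, f2$pi)
  expect_equal(f1$theta, f2$theta)
  expect_equal(f1$epsilon, f2$epsilon)
})

test_that("edit posterior matches direct Bayes computation and is monotone in alt count", {
  fit <- make_fit(pi = 0.3, theta = 0.5, epsilon = 0.002)
  p <- edit_posterior(100, 50, fit)
  direct <- 0.3 * dbinom(50, 100, 0.5) /
    (0.3 * dbinom(50, 100, 0.5) + 0.7 * dbinom(50, 100, 0.002))
  expect_equal(p, direct)
  expect_gt(p, 0.999)
  post <- edit_posterior(rep(100, 21), 0:20, fit)
  expect_true(all(diff(post) >= -1e-12))
})

test_that("edit calling enforces depth, alt-count, posterior and control thresholds", {
  fit <- make_fit(pi = 0.3, theta = 0.5, epsilon = 0.002)
  counts <- data.frame(site_id = c("s1", "s2", "s3", "s4"),
                       sample_id = "a",
                       depth = c(100L, 8L, 1000L, 100L),
                       alt_count = c(50L, 8L, 2L, 50L))
  calls <- call_edits(counts, fit,
                      control_vafs = c(s4 = 0.9))  # s4 fails the background filter
  expect_true(calls$called[calls$site_id == "s1"])
  expect_false(calls$called[calls$site_id == "s2"])  # depth not > 10
  expect_false(calls$called[calls$site_id == "s3"])  # alt count not > 2
  expect_false(calls$called[calls$site_id == "s4"])  # below control VAF
})

test_that("planted edits are recovered with high precision and recall", {
  spec <- fixture_spec(n_sites = 60, n_samples = 4, depth_mean = 100,
                       background_error = 0.002, edited_vaf = 0.5,
                       edited_fraction = 0.3, seed = 21)
  fx <- generate_fixture(spec)
  fit <- fit_mixture(fx$site_counts)
  calls <- call_edits(fx$site_counts, fit)
  truth_key <- paste(fx$truth$site_id, fx$truth$sample_id)
  called_key <- paste(calls$site_id, calls$sample_id)[calls$called]
  precision <- mean(called_key %in% truth_key)
  recall <- mean(truth_key %in% called_key)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)
})

test_that("paired window Cs merge by averaging allele fractions", {
  a <- data.frame(site_id = "p1", sample_id = "x", depth = 100L, alt_count = 10L)
  b <- data.frame(site_id = "p2", sample_id = "x", depth = 50L, alt_count = 15L)
  m <- average_paired_c(a, b)
  expect_equal(m$vaf, 0.2)
  expect_equal(m$depth, 50L)      # conservative minimum
  same <- average_paired_c(a, a)
  expect_equal(same$vaf, 0.1)     # idempotent on identical VAFs
  zero <- data.frame(site_id = "p3", sample_id = "x", depth = 0L, alt_count = 0L)
  expect_equal(average_paired_c(a, zero)$vaf, 0.1)  # covered-position fallback
  a$target_id <- "t1"; b2 <- b; b2$target_id <- "t2"
  expect_error(average_paired_c(a, b2), "different targets")
})

test_that("site probabilities normalize mean efficiencies to sum one", {
  m <- matrix(c(0.1, 0.1, 0.3, 0.3), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), NULL))
  p <- site_probabilities(m)
  expect_equal(unname(p), c(0.25, 0.75))
  expect_equal(sum(p), 1)
  expect_equal(unname(site_probabilities(m[1, , drop = FALSE])), 1)
  # permutation equivariance
  expect_equal(site_probabilities(m[c(2, 1), ]), p[c(2, 1)])
  expect_error(site_probabilities(matrix(0, 2, 2)), "all-zero")
})

test_that("site filtering removes saturated, blacklisted and correlated sites", {
  set.seed(13)
  m <- matrix(runif(10 * 50, 0, 0.4), nrow = 10,
              dimnames = list(paste0("s", 1:10), NULL))
  m["s1", ] <- runif(50, 0.85, 0.95)          # saturated
  m["s3", ] <- m["s2", ]                      # perfectly correlated pair
  kept <- filter_sites(m, saturation_probability = Inf)
  expect_false("s1" %in% kept)
  expect_true("s2" %in% kept)                 # lower-index site survives
  expect_false("s3" %in% kept)
  expect_true(all(kept %in% rownames(m)))
  # independent random columns are retained, matching a direct R^2 oracle
  r2 <- cor(t(m[kept, ]))^2
  expect_true(all(r2[upper.tri(r2)] <= 0.8))
  # idempotence
  kept2 <- filter_sites(m[kept, , drop = FALSE], saturation_probability = Inf)
  expect_equal(kept2, kept)
  # blacklist removal
  expect_false("s2" %in% filter_sites(m, blacklist = "s2",
                                      saturation_probability = Inf))
})

test_that("the normalized-probability rule also triggers removal", {
  m <- matrix(0.01, nrow = 5, ncol = 4, dimnames = list(paste0("s", 1:5), NULL))
  m["s5", ] <- 0.5   # carries most of the probability mass (> 0.004 normalized)
  kept <- filter_sites(m)
  expect_false("s5" %in% kept)
})

test_that("CIGAR-like barcodes encode ordinals and round-trip", {
  sites <- paste0("site", 1:12)
  expect_equal(encode_barcode(sites[c(1, 10)], sites), "1E10E")
  expect_equal(encode_barcode(character(), sites), "")
  expect_equal(decode_barcode("1E10E", sites), sites[c(1, 10)])
  expect_equal(decode_barcode("", sites), character())
  expect_error(encode_barcode("nope", sites), "unknown site_id")
  expect_error(decode_barcode("1F", sites), "malformed")
  set.seed(8)
  for (i in 1:20) {
    ed <- sample(sites, sample(0:12, 1))
    expect_setequal(decode_barcode(encode_barcode(ed, sites), sites), ed)
  }
})

test_that("bulk-to-single-cell probability transfer restricts and renormalizes", {
  p <- setNames(c(0.5, 0.3, 0.2), c("a", "b", "c"))
  tr <- transfer_probabilities(p, c("a", "c", "zzz"))
  expect_equal(sum(tr), 1)
  expect_equal(unname(tr["a"] / tr["c"]), 0.5 / 0.2)
  expect_error(transfer_probabilities(p, "zzz"), "no shared sites")
})
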