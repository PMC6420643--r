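#' Fit a binomial mixture model to per-site C>T counts
#'
#' Models the alt-read count k at a site of depth n as a two-component mixture,
#' P(k | n) = pi * Binom(k; n, theta) + (1 - pi) * Binom(k; n, epsilon): a
#' background component at the sequencing/deamination error rate epsilon and an
#' edited component at allele fraction theta. Parameters are estimated by EM.
#' When `ploidy_levels` is supplied (e.g. `c(1/3, 2/3, 1)` for a triploid
#' locus) the edited component is an equal-weight mixture over those fixed
#' allele-fraction levels and only pi and epsilon are free.
#'
#' EM runs from `n_restarts` jittered initializations (epsilon 0.005, theta
#' 0.5, pi 0.1 by default) and keeps the best log-likelihood; convergence is
#' declared when the log-likelihood improves by less than `tol` (1e-8) or
#' after `max_iter` (500) iterations. All-zero alt counts give a degenerate
#' fit with pi driven to ~0, flagged via `degenerate`, not an error.
#'
#' @param counts Data.frame with columns `depth` and `alt_count` (one row per
#'   site x sample observation); at least 10 rows with depth > 0.
#' @param ploidy_levels Optional numeric vector of edited allele fractions.
#' @param init Named list of starting values `epsilon`, `theta`, `pi`.
#' @param n_restarts Number of jittered EM restarts (default 3; restart 1 uses
#'   `init` exactly, further restarts jitter deterministically).
#' @param tol,max_iter EM convergence controls.
#' @return Object of class `mixture_fit`: list with `pi`, `theta` (scalar, or
#'   the fixed level vector under ploidy mode), `epsilon`, `loglik`, `n_iter`,
#'   `converged`, `degenerate`, `ploidy_mode`.
#' @export
fit_mixture <- function(counts, ploidy_levels = NULL,
                        init = list(epsilon = 0.005, theta = 0.5, pi = 0.1),
                        n_restarts = 3L, tol = 1e-8, max_iter = 500L) {
  stopifnot(is.data.frame(counts), all(c("depth", "alt_count") %in% names(counts)))
  k <- as.numeric(counts$alt_count)
  n <- as.numeric(counts$depth)
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  if (length(n) < 10L) stop("need at least 10 sites with depth > 0")
  if (any(k > n)) stop("alt_count exceeds depth")

  # deterministic jitter factors for restarts (no RNG dependence)
  jit <- list(c(1, 1, 1), c(0.4, 0.8, 2), c(2.5, 1.2, 0.5))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    f <- jit[[((r - 1L) %% length(jit)) + 1L]]
    fit <- .em_binom_mix(k, n,
                         eps0 = min(0.2, init$epsilon * f[1L]),
                         th0 = min(0.95, init$theta * f[2L]),
                         pi0 = min(0.9, init$pi * f[3L]),
                         levels = ploidy_levels, tol = tol, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$ploidy_mode <- !is.null(ploidy_levels)
  best$degenerate <- all(k == 0) || best$pi < 1e-4
  class(best) <- "mixture_fit"
  best
}

## log density of the edited component (equal-weight mixture over levels when set)
.ldens_edited <- function(k, n, theta, levels) {
  if (is.null(levels)) {
    dbinom(k, n, theta, log = TRUE)
  } else {
    m <- vapply(levels, function(th) dbinom(k, n, th, log = TRUE),
                numeric(length(k)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(k))
    mx <- apply(m, 1L, max)
    mx + log(rowMeans(exp(m - mx)))
  }
}

.em_binom_mix <- function(k, n, eps0, th0, pi0, levels, tol, max_iter) {
  eps <- eps0; th <- th0; pp <- pi0
  ll_old <- -Inf; it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    l1 <- .ldens_edited(k, n, th, levels) + log(pp)
    l0 <- dbinom(k, n, eps, log = TRUE) + log1p(-pp)
    mx <- pmax(l1, l0)
    lse <- mx + log(exp(l1 - mx) + exp(l0 - mx))
    ll <- sum(lse)
    gamma <- exp(l1 - lse)
    # M-step
    pp <- mean(gamma)
    pp <- min(max(pp, 1e-10), 1 - 1e-10)
    eps <- sum((1 - gamma) * k) / max(sum((1 - gamma) * n), .Machine$double.eps)
    eps <- min(max(eps, 1e-8), 1 - 1e-8)
    if (is.null(levels)) {
      th <- sum(gamma * k) / max(sum(gamma * n), .Machine$double.eps)
      th <- min(max(th, 1e-8), 1 - 1e-8)
      if (th < eps) {  # keep the edited component the high-fraction one
        tmp <- th; th <- eps; eps <- tmp
        pp <- 1 - pp
      }
    }
    if (ll - ll_old < tol && it > 1L) {
      converged <- ll - ll_old >= 0 || abs(ll - ll_old) < sqrt(tol)
      break
    }
    if (it >= max_iter) break
    ll_old <- ll
  }
  list(pi = pp, theta = if (is.null(levels)) th else levels,
       epsilon = eps, loglik = ll, n_iter = it, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Binomial mixture fit\n")
  cat(sprintf("  pi      = %.4g\n", x$pi))
  cat(sprintf("  theta   = %s\n", paste(signif(x$theta, 4), collapse = ", ")))
  cat(sprintf("  epsilon = %.4g\n", x$epsilon))
  cat(sprintf("  loglik  = %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  if (isTRUE(x$degenerate)) cat("  note: degenerate fit (no edited signal)\n")
  invisible(x)
}

#' Posterior probability that counts come from the edited component
#'
#' @param depth,alt_count Numeric vectors of depths and alt counts.
#' @param fit A `mixture_fit`.
#' @return Posterior responsibilities of the edited component in \[0, 1\].
#' @export
edit_posterior <- function(depth, alt_count, fit) {
  k <- as.numeric(alt_count); n <- as.numeric(depth)
  levels <- if (isTRUE(fit$ploidy_mode)) fit$theta else NULL
  theta <- if (isTRUE(fit$ploidy_mode)) NA_real_ else fit$theta
  l1 <- .ldens_edited(k, n, theta, levels) + log(fit$pi)
  l0 <- dbinom(k, n, fit$epsilon, log = TRUE) + log1p(-fit$pi)
  mx <- pmax(l1, l0)
  post <- exp(l1 - mx) / (exp(l1 - mx) + exp(l0 - mx))
  post[n == 0] <- 0
  post
}

#' Call edits per site and sample
#'
#' A site/sample observation is called edited when all of the confidence
#' thresholds hold: depth > `min_depth` (default 10), alt count > `min_alt`
#' (default 2), posterior probability of the edited mixture component >=
#' `min_posterior` (default 0.95), and the observed allele fraction exceeds the
#' background-control allele fraction for that site (missing control treated
#' as 0).
#'
#' @param counts Data.frame with `site_id`, `sample_id`, `depth`, `alt_count`.
#' @param fit A `mixture_fit` from [fit_mixture()].
#' @param control_vafs Optional named numeric vector mapping site_id to the
#'   background-control allele fraction.
#' @param min_depth,min_alt,min_posterior Confidence thresholds (strict
#'   inequalities for depth and alt count, per the calling rule depth > 10x
#'   and variant allele count > 2; posterior is >=).
#' @return Data.frame `site_id`, `sample_id`, `depth`, `alt_count`, `vaf`,
#'   `posterior`, `called`.
#' @export
call_edits <- function(counts, fit, control_vafs = NULL,
                       min_depth = 10L, min_alt = 2L, min_posterior = 0.95) {
  stopifnot(all(c("site_id", "sample_id", "depth", "alt_count") %in% names(counts)))
  post <- edit_posterior(counts$depth, counts$alt_count, fit)
  vaf <- ifelse(counts$depth > 0, counts$alt_count / counts$depth, 0)
  ctrl <- rep(0, nrow(counts))
  if (!is.null(control_vafs)) {
    hit <- match(counts$site_id, names(control_vafs))
    ctrl[!is.na(hit)] <- control_vafs[hit[!is.na(hit)]]
  }
  called <- counts$depth > min_depth & counts$alt_count > min_alt &
    post >= min_posterior & vaf > ctrl
  data.frame(site_id = counts$site_id, sample_id = counts$sample_id,
             depth = counts$depth, alt_count = counts$alt_count,
             vaf = vaf, posterior = post, called = called,
             stringsAsFactors = FALSE)
}

#' Merge the two window Cs of one spacer into a single editing site
#'
#' Deamination in the editing window is processive, so the two Cs of a target
#' behave as one site: the merged allele fraction is the mean of the two VAFs
#' and the merged depth is the conservative minimum. If one position has zero
#' depth, the merged VAF falls back to the covered position's VAF.
#'
#' @param a,b Single-row data.frames (or lists) with `site_id`, `sample_id`,
#'   `depth`, `alt_count`; both positions must come from the same target, which
#'   the caller asserts via a shared `target_id` field if present.
#' @param merged_id Site id for the merged record; default joins the two ids.
#' @return One-row data.frame with `site_id`, `sample_id`, `depth`, `vaf`,
#'   `alt_count` (rounded to the merged depth scale).
#' @export
average_paired_c <- function(a, b, merged_id = NULL) {
  if (!is.null(a$target_id) && !is.null(b$target_id) &&
      !identical(a$target_id, b$target_id)) {
    stop("positions come from different targets")
  }
  if (!identical(a$sample_id, b$sample_id)) stop("positions from different samples")
  vaf_a <- if (a$depth > 0) a$alt_count / a$depth else NA_real_
  vaf_b <- if (b$depth > 0) b$alt_count / b$depth else NA_real_
  if (is.na(vaf_a) && is.na(vaf_b)) {
    vaf <- 0
  } else if (is.na(vaf_a)) {
    vaf <- vaf_b
  } else if (is.na(vaf_b)) {
    vaf <- vaf_a
  } else {
    vaf <- (vaf_a + vaf_b) / 2
  }
  depth <- min(a$depth, b$depth)
  if (depth == 0) depth <- max(a$depth, b$depth)
  if (is.null(merged_id)) merged_id <- paste(a$site_id, b$site_id, sep = "|")
  data.frame(site_id = merged_id, sample_id = a$sample_id,
             depth = depth, alt_count = round(vaf * depth), vaf = vaf,
             stringsAsFactors = FALSE)
}

#' Normalized per-site editing probabilities
#'
#' Each site's mean editing efficiency across samples, normalized so the
#' probabilities over all sites sum to 1. These site editing probabilities are
#' what the simulator's site-bias model is calibrated against and what the
#' saturation filter thresholds.
#'
#' @param efficiency_matrix Numeric matrix, sites x samples, of per-sample
#'   editing efficiencies (VAFs); rownames are site ids.
#' @return Named numeric vector summing to 1.
#' @export
site_probabilities <- function(efficiency_matrix) {
  m <- as.matrix(efficiency_matrix)
  if (nrow(m) < 1L) stop("need at least one site")
  mu <- rowMeans(m)
  tot <- sum(mu)
  if (tot == 0) stop("all-zero efficiency matrix; probabilities undefined")
  mu / tot
}

#' Select confident sites for lineage reconstruction
#'
#' Removes, in order: (i) blacklisted sites; (ii) saturated sites, i.e. mean
#' editing efficiency > `saturation_efficiency` (default 0.8) *or* normalized
#' site editing probability > `saturation_probability` (default 0.004) --
#' saturated sites are shared by almost every clone and carry no lineage
#' signal; (iii) one site of each highly correlated pair (squared Pearson
#' correlation of per-sample efficiencies > `corr_threshold`, default 0.8),
#' keeping the earlier site in matrix order, to reduce the chance that two
#' cells accidentally share edits.
#'
#' @param efficiency_matrix Numeric matrix, sites x samples (>= 2 samples);
#'   rownames are site ids.
#' @param probabilities Optional precomputed [site_probabilities()]; computed
#'   from the matrix when `NULL`.
#' @param corr_threshold Squared-correlation removal threshold, default 0.8.
#' @param saturation_efficiency Mean-efficiency removal threshold, default 0.8.
#' @param saturation_probability Normalized-probability removal threshold,
#'   default 0.004.
#' @param blacklist Character vector of site ids to drop unconditionally.
#' @return Character vector of retained site ids (subset of rownames, in
#'   original order). Applying the filter to the retained submatrix is
#'   idempotent.
#' @export
filter_sites <- function(efficiency_matrix, probabilities = NULL,
                         corr_threshold = 0.8, saturation_efficiency = 0.8,
                         saturation_probability = 0.004, blacklist = character()) {
  m <- as.matrix(efficiency_matrix)
  if (ncol(m) < 2L) stop("need an efficiency matrix over at least 2 samples")
  if (is.null(rownames(m))) rownames(m) <- paste0("site", seq_len(nrow(m)))
  keep <- !(rownames(m) %in% blacklist)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(character())
  if (is.null(probabilities)) {
    probabilities <- tryCatch(site_probabilities(m), error = function(e) {
      setNames(rep(0, nrow(m)), rownames(m))
    })
  }
  p <- probabilities[rownames(m)]
  saturated <- rowMeans(m) > saturation_efficiency | p > saturation_probability
  m <- m[!saturated, , drop = FALSE]
  if (nrow(m) <= 1L) return(rownames(m))
  cc <- suppressWarnings(cor(t(m)))
  r2 <- cc^2
  r2[is.na(r2)] <- 0
  drop <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(m) - 1L)) {
    if (drop[i]) next
    hits <- which(r2[i, ] > corr_threshold)
    drop[hits[hits > i]] <- TRUE
  }
  rownames(m)[!drop]
}

#' Encode a sample's edits as a CIGAR-like barcode string
#'
#' Each edited site is written as its 1-based ordinal in the shared site
#' ordering followed by `E`; ordinals appear in ascending order. `"1E10E"`
#' means the first and the tenth C position of the target ordering are edited;
#' no edits gives `""`.
#'
#' @param edits Character vector of edited site ids for one sample.
#' @param site_order Character vector fixing the shared site ordering.
#' @return Single barcode string.
#' @seealso [decode_barcode()]
#' @export
encode_barcode <- function(edits, site_order) {
  if (length(edits) == 0L) return("")
  ord <- match(edits, site_order)
  if (anyNA(ord)) {
    stop("unknown site_id: ", paste(edits[is.na(ord)], collapse = ", "))
  }
  paste0(sort(unique(ord)), "E", collapse = "")
}

#' Decode a CIGAR-like barcode string back to site ids
#'
#' @param barcode Barcode string such as `"1E10E"` (possibly `""`).
#' @param site_order Character vector fixing the shared site ordering.
#' @return Character vector of edited site ids (ascending ordinal order).
#' @export
decode_barcode <- function(barcode, site_order) {
  if (!nzchar(barcode)) return(character())
  if (!grepl("^([0-9]+E)+$", barcode)) stop("malformed barcode string: ", barcode)
  ord <- as.integer(regmatches(barcode, gregexpr("[0-9]+", barcode))[[1L]])
  if (any(ord < 1L | ord > length(site_order))) stop("barcode ordinal out of range")
  site_order[ord]
}

#' Restrict bulk site editing probabilities to single-cell shared sites
#'
#' Single-cell libraries have a different read structure than bulk, so site
#' editing probabilities estimated from bulk data are transferred to single
#' cells only for the sites observed in both; probabilities are renormalized
#' over the shared set.
#'
#' @param bulk_probabilities Named probability vector from
#'   [site_probabilities()] on bulk data.
#' @param sc_site_ids Site ids observed in the single-cell data.
#' @return Named probability vector over the shared sites, summing to 1.
#' @export
transfer_probabilities <- function(bulk_probabilities, sc_site_ids) {
  shared <- intersect(names(bulk_probabilities), sc_site_ids)
  if (length(shared) == 0L) stop("no shared sites between bulk and single-cell data")
  p <- bulk_probabilities[shared]
  p / sum(p)
}
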