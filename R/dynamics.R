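#' Estimate the per-hour editing rate from a time course
#'
#' Fits W(t) = exp(-r t) to the fraction of unedited (wild-type) target sites
#' over time, with the t = 0 point pinned at a wild-type fraction of 1. The
#' rate is first obtained in log space (linear regression of log W on t through
#' the origin) and then refined by nonlinear least squares
#' (`minpack.lm::nlsLM`) on the original scale. Replicates are pooled as
#' independent points.
#'
#' @param times Numeric vector of sampling times in hours (>= 0).
#' @param wildtype_fraction Numeric vector in (0, 1\] of unedited-site
#'   fractions, same length as `times`.
#' @return Object of class `rate_fit`: list with `rate` (edits per hour,
#'   >= 0) and `residual` (sum of squared errors of the exponential fit).
#' @examples
#' t <- c(4, 8, 12, 16, 20, 24, 30, 36, 42, 48)
#' fit_editing_rate(t, exp(-0.06 * t))
#' @export
fit_editing_rate <- function(times, wildtype_fraction) {
  t <- as.numeric(times)
  w <- as.numeric(wildtype_fraction)
  if (length(t) != length(w)) stop("times and fractions must have equal length")
  if (length(t) < 3L) stop("need at least 3 time points")
  if (any(w <= 0 | w > 1)) stop("wild-type fractions must lie in (0, 1]")
  if (any(t < 0)) stop("times must be non-negative")
  o <- order(t)
  if (any(diff(w[o]) > 0)) {
    warning("wild-type fraction increases over time; fit returned anyway")
  }
  pos <- t > 0
  r0 <- if (any(pos)) max(0, -sum(t[pos] * log(w[pos])) / sum(t[pos]^2)) else 0
  r <- r0
  if (r0 > 0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(w ~ exp(-r * t), start = list(r = r0),
                        lower = 0, data = data.frame(t = t, w = w)),
      error = function(e) NULL)
    if (!is.null(fit)) r <- coef(fit)[["r"]]
  }
  structure(list(rate = r, residual = sum((w - exp(-r * t))^2)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Editing rate: %.6g edits per hour (residual SSE %.3g)\n",
              x$rate, x$residual))
  invisible(x)
}

#' Read an editing time course from TSV
#'
#' Expects columns `hours`, `wildtype_fraction`, and optionally `replicate`;
#' replicates are pooled.
#'
#' @param path TSV path.
#' @return Data.frame with `hours` and `wildtype_fraction`.
#' @export
read_timecourse_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("hours", "wildtype_fraction")
  if (!all(need %in% names(df))) {
    stop("time-course TSV needs columns: ", paste(need, collapse = ", "))
  }
  df[, intersect(c(need, "replicate"), names(df)), drop = FALSE]
}
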