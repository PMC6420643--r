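#' Screen sequences for deaminase-targetable protospacers
#'
#' Scans every 20-nt window adjacent to an NGG PAM and keeps windows that carry
#' at least `min_window_c` cytosines inside the editing window, protospacer
#' positions 4-8 counted from the PAM-distal end (position 20 abuts the PAM).
#' These are the sites a cytidine deaminase fused to nickase Cas9 can convert,
#' so only spacers with an editable C are useful as lineage barcodes.
#'
#' Coordinates are 0-based half-open on the forward strand of each input
#' sequence; a reverse-strand hit is reported at the forward-strand interval its
#' protospacer occupies, with `strand == "-"`. Any `N` inside the protospacer or
#' PAM disqualifies the window.
#'
#' @param sequences Named character vector of DNA sequences (A/C/G/T/N), a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param both_strands Scan the reverse complement as well? Default `TRUE`.
#' @param min_window_c Minimum number of Cs required in window positions 4-8.
#' @return A data.frame with columns `sequence_id`, `start` (0-based start of
#'   the 20-nt protospacer on the forward strand), `strand`, `spacer` (5'->3'),
#'   `pam`, and list-column `window_c_positions` (1-based PAM-distal positions
#'   in 4..8 where the spacer has a C).
#' @examples
#' seqs <- c(s1 = "AAAAACTCGATCGATCGATCGATCTGGAAAA")
#' scan_protospacers(seqs)
#' @export
scan_protospacers <- function(sequences, both_strands = TRUE, min_window_c = 1L) {
  sequences <- .as_named_seqs(sequences)
  if (length(sequences) == 0L) {
    return(.empty_hits())
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("sequences contain characters other than A/C/G/T/N: ",
         paste(names(sequences)[bad], collapse = ", "))
  }
  out <- vector("list", 2L * length(sequences))
  k <- 0L
  for (i in seq_along(sequences)) {
    id <- names(sequences)[i]
    s <- sequences[[i]]
    k <- k + 1L
    out[[k]] <- .scan_strand(s, id, "+", min_window_c)
    if (both_strands) {
      k <- k + 1L
      out[[k]] <- .scan_strand(rev_comp(s), id, "-", min_window_c, orig_len = nchar(s))
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  if (is.null(res) || nrow(res) == 0L) {
    return(.empty_hits())
  }
  res <- res[order(res$sequence_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_hits <- function() {
  df <- data.frame(sequence_id = character(), start = integer(),
                   strand = character(), spacer = character(),
                   pam = character(), stringsAsFactors = FALSE)
  df$window_c_positions <- list()
  df
}

## One-strand scan over the given (possibly reverse-complemented) string.
## For strand "-", `orig_len` maps window starts back to forward coordinates.
.scan_strand <- function(s, id, strand, min_window_c, orig_len = NULL) {
  L <- nchar(s)
  if (L < 23L) return(NULL)
  starts <- seq_len(L - 22L)                        # 1-based on scanned strand
  spacer <- substring(s, starts, starts + 19L)
  pam    <- substring(s, starts + 20L, starts + 22L)
  ok <- substring(pam, 2L, 2L) == "G" & substring(pam, 3L, 3L) == "G" &
    !grepl("N", spacer, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
  if (!any(ok)) return(NULL)
  starts <- starts[ok]; spacer <- spacer[ok]; pam <- pam[ok]
  win_pos <- lapply(gregexpr("C", substring(spacer, 4L, 8L), fixed = TRUE),
                    function(m) if (m[1L] == -1L) integer() else as.integer(m) + 3L)
  keep <- lengths(win_pos) >= min_window_c
  if (!any(keep)) return(NULL)
  starts <- starts[keep]; spacer <- spacer[keep]; pam <- pam[keep]
  win_pos <- win_pos[keep]
  fwd_start <- if (strand == "+") starts - 1L else orig_len - (starts - 1L) - 20L
  df <- data.frame(sequence_id = id, start = as.integer(fwd_start),
                   strand = strand, spacer = spacer, pam = pam,
                   stringsAsFactors = FALSE)
  df$window_c_positions <- win_pos
  df
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @export
rev_comp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("acgtnACGTN", "TGCANTGCAN", s), "")[[1L]])
    paste(chars, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Rank spacers by perfect-match multiplicity
#'
#' Groups identical spacer strings from [scan_protospacers()], counts their
#' perfect-match hits across the input sequences, and ranks them in descending
#' count order. Spacers matching many interspersed target copies are the useful
#' sgRNA candidates: one guide then barcodes many loci at once.
#'
#' @param hits Data.frame from [scan_protospacers()] (only `spacer` is used).
#' @param min_matches Keep spacers with at least this many perfect-match hits
#'   (default 2, i.e. multi-copy spacers only).
#' @return Data.frame with `spacer`, `match_count`, `rank` (1..K, descending
#'   count, ties broken by lexicographic spacer order).
#' @export
rank_spacers <- function(hits, min_matches = 2L) {
  stopifnot(is.data.frame(hits), "spacer" %in% names(hits))
  if (nrow(hits) == 0L) {
    return(data.frame(spacer = character(), match_count = integer(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(hits$spacer)
  tab <- tab[tab >= min_matches]
  spacer <- names(tab)
  cnt <- as.integer(tab)
  o <- order(-cnt, spacer)
  data.frame(spacer = spacer[o], match_count = cnt[o],
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Mean pairwise identity of equal-length DNA strings
#'
#' Position-wise, ungapped comparison: for each unordered pair the fraction of
#' matching positions, averaged over all pairs. Strings must share one length;
#' no alignment is attempted.
#'
#' @param strings Character vector of >= 2 equal-length DNA strings.
#' @return Mean pairwise identity fraction in \[0, 1\].
#' @export
pairwise_similarity <- function(strings) {
  if (length(strings) < 2L) stop("need at least two strings")
  L <- unique(nchar(strings))
  if (length(L) != 1L) stop("strings must have equal length for position-wise comparison")
  m <- do.call(rbind, strsplit(strings, ""))
  n <- length(strings)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + mean(m[i, ] == m[j, ])
    }
  }
  tot / (n * (n - 1L) / 2L)
}

#' Write protospacer hits as TSV
#'
#' Columns: sequence_id, start, strand, spacer, pam, window_c_positions (comma
#' list of 1-based PAM-distal positions).
#'
#' @param hits Data.frame from [scan_protospacers()].
#' @param path Output file path.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- hits
  out$window_c_positions <- vapply(hits$window_c_positions,
                                   function(p) paste(p, collapse = ","),
                                   character(1L))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.as_named_seqs <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    x <- toupper(as.character(sequences))
    return(x)
  }
  if (is.character(sequences) && length(sequences) == 1L &&
      !grepl("^[ACGTNacgtn]+$", sequences) && file.exists(sequences)) {
    x <- tryCatch(Biostrings::readDNAStringSet(sequences),
                  error = function(e) stop("malformed FASTA: ", conditionMessage(e)))
    return(.as_named_seqs(x))
  }
  if (!is.character(sequences)) stop("sequences must be character, DNAStringSet, or FASTA path")
  x <- toupper(sequences)
  if (is.null(names(x)) && length(x) > 0L) names(x) <- paste0("seq", seq_along(x))
  x
}
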