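#' Read per-site base counts from samtools mpileup text
#'
#' Parses the 6-column mpileup dialect (chrom, 1-based pos, ref, depth, read
#' bases, base qualities), decoding '.'/',' reference matches, ACGT/acgt
#' mismatches, read start (`^` + mapping quality), read end (`$`), indel
#' (`+n<seq>` / `-n<seq>`) and deletion placeholder (`*`) markers. C>T edits
#' are counted strand-consistently: at a reference `C` the alt reads are
#' `T`/`t`; at a reference `G` (editing-window C on the minus strand) the alt
#' reads are `A`/`a` -- the same chemical event read from the other strand.
#'
#' @param path Pileup file path.
#' @param sample_id Sample label attached to every row (default: file base
#'   name).
#' @return Data.frame with `site_id` (chrom:pos), `sample_id`, `ref`, `depth`
#'   (column 4 of the pileup), `alt_count`, `vaf`.
#' @export
read_pileup <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(f) < 4L) stop("malformed pileup line ", i, ": ", lines[i])
    pos <- suppressWarnings(as.integer(f[2L]))
    depth <- suppressWarnings(as.integer(f[4L]))
    if (is.na(pos) || is.na(depth)) stop("malformed pileup line ", i, ": ", lines[i])
    ref <- toupper(f[3L])
    bases <- if (length(f) >= 5L) f[5L] else ""
    cnt <- .pileup_base_counts(bases, line = i)
    alt <- switch(ref,
                  C = cnt["T"] + cnt["t"],
                  G = cnt["A"] + cnt["a"],
                  0L)
    out[[i]] <- data.frame(site_id = paste0(f[1L], ":", pos),
                           sample_id = sample_id, ref = ref,
                           depth = depth, alt_count = as.integer(alt),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(site_id = character(), sample_id = character(),
                      ref = character(), depth = integer(),
                      alt_count = integer(), stringsAsFactors = FALSE)
  }
  res$vaf <- ifelse(res$depth > 0, res$alt_count / res$depth, 0)
  res
}

## decode one pileup read-bases string into per-symbol counts
.pileup_base_counts <- function(bases, line = NA) {
  s <- gsub("\\^.", "", bases)     # read starts carry a mapq character
  s <- gsub("\\$", "", s, fixed = FALSE)
  repeat {                          # strip +n<seq> / -n<seq> indel records
    m <- regexpr("[+-][0-9]+", s)
    if (m == -1L) break
    len <- as.integer(substr(s, m + 1L, m + attr(m, "match.length") - 1L))
    tail_start <- as.integer(m) + attr(m, "match.length") + len
    s <- paste0(substr(s, 1L, as.integer(m) - 1L), substring(s, tail_start))
  }
  chars <- strsplit(s, "")[[1L]]
  allowed <- c(".", ",", "*", "A", "C", "G", "T", "N", "a", "c", "g", "t", "n")
  if (length(chars) && any(!chars %in% allowed)) {
    stop("malformed pileup base string on line ", line, ": ", bases)
  }
  tab <- table(factor(chars, levels = allowed))
  setNames(as.integer(tab), allowed)
}

#' Read precomputed site counts from TSV
#'
#' Expects columns `site_id`, `sample_id`, `depth`, `alt_count`.
#'
#' @param path TSV path.
#' @return Data.frame with a derived `vaf` column.
#' @export
read_site_counts_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "sample_id", "depth", "alt_count")
  if (!all(need %in% names(df))) {
    stop("site-count TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$alt_count > df$depth)) stop("alt_count exceeds depth")
  df$vaf <- ifelse(df$depth > 0, df$alt_count / df$depth, 0)
  df
}

#' Write/read Newick trees
#'
#' Thin wrappers over ape with strict error behavior: unreadable or
#' syntactically broken files raise errors instead of returning `NULL`.
#' Internal node labels (e.g. bootstrap supports) survive the round trip.
#'
#' @param tree For writing: an `ape::phylo`, an `hclust`, the list returned by
#'   [bootstrap_support()], or an `edit_tree`.
#' @param path File path.
#' @return `read_newick` returns an `ape::phylo`; `write_newick` returns the
#'   path invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "edit_tree")) {
    write_tree_newick(tree, path)
    return(invisible(path))
  }
  if (is.list(tree) && !is.null(tree$phylo)) tree <- tree$phylo
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop("cannot serialize object of class ", class(tree)[1L])
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty Newick file: ", path)
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) stop("unbalanced parentheses in Newick file: ", path)
  tr <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("failed to parse Newick file: ", path)
  tr
}

#' Write barcode calls / barcode matrix as TSV
#'
#' @param barcodes Samples-x-sites binary matrix.
#' @param path Output TSV path; one row per sample with `sample_id`,
#'   `cigar_string`, and the 0/1 site vector.
#' @export
write_barcode_tsv <- function(barcodes, path) {
  m <- as.matrix(barcodes) > 0
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("site", seq_len(ncol(m)))
  cigar <- vapply(seq_len(nrow(m)), function(i) {
    encode_barcode(colnames(m)[m[i, ]], colnames(m))
  }, character(1L))
  out <- data.frame(sample_id = rownames(m), cigar_string = cigar,
                    m * 1L, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode matrix written by [write_barcode_tsv()]
#'
#' @param path TSV path.
#' @return Samples-x-sites logical matrix.
#' @export
read_barcode_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("barcode TSV needs a sample_id column")
  sites <- setdiff(names(df), c("sample_id", "cigar_string"))
  m <- as.matrix(df[, sites, drop = FALSE]) > 0
  rownames(m) <- df$sample_id
  m
}
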