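#' Specification for a seeded synthetic data fixture
#'
#' Describes the data shapes the pipeline consumes so every stage can be tested
#' without external downloads: pileup columns with a low background C>T error
#' rate plus true edits at a defined allele fraction, UMI read families with
#' sequencing errors, and the resulting per-sample barcode matrix.
#'
#' @param n_sites,n_samples Numbers of target sites and samples.
#' @param depth_mean Mean sequencing depth per site (Poisson).
#' @param background_error Background C>T error rate, default 0.002.
#' @param edited_vaf Allele fraction of true edits, default 0.5.
#' @param edited_fraction Probability that a site/sample pair carries a true
#'   edit, default 0.15.
#' @param umi_length UMI length in bases, default 10.
#' @param n_molecules,reads_per_molecule UMI fixture shape.
#' @param umi_error_rate Probability that a read's UMI carries one sequencing
#'   error, default 0.1.
#' @param seq_error_rate Per-base error rate on read sequences, default 0.005.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_sites = 50L, n_samples = 4L, depth_mean = 100,
                         background_error = 0.002, edited_vaf = 0.5,
                         edited_fraction = 0.15, umi_length = 10L,
                         n_molecules = 30L, reads_per_molecule = 6L,
                         umi_error_rate = 0.1, seq_error_rate = 0.005,
                         seed = 1L) {
  stopifnot(n_sites >= 1, n_samples >= 1, depth_mean >= 1,
            background_error >= 0, background_error <= 1,
            edited_vaf >= 0, edited_vaf <= 1,
            edited_fraction >= 0, edited_fraction <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a seeded synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @return List with `site_counts` (long data.frame of site_id/sample_id/
#'   depth/alt_count/vaf), `truth` (data.frame of truly edited site/sample
#'   pairs; empty when `edited_fraction = 0`), `pileup_lines` (named list,
#'   per-sample character vectors of mpileup text), `umi_reads` (data.frame
#'   read_id/umi/sequence with per-family errors and one-off UMI variants),
#'   `umi_truth_molecules` (true molecule count), and `barcodes`
#'   (samples x sites logical matrix of true edits).
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  sites <- sprintf("L1:%d", seq_len(spec$n_sites) * 100L)
  samples <- sprintf("sample%02d", seq_len(spec$n_samples))

  edited <- matrix(runif(spec$n_sites * spec$n_samples) < spec$edited_fraction,
                   spec$n_sites, spec$n_samples,
                   dimnames = list(sites, samples))
  depth <- matrix(rpois(spec$n_sites * spec$n_samples, spec$depth_mean),
                  spec$n_sites, spec$n_samples)
  vaf_true <- ifelse(edited, spec$edited_vaf, spec$background_error)
  alt <- matrix(rbinom(length(depth), as.vector(depth), as.vector(vaf_true)),
                spec$n_sites, spec$n_samples)

  site_counts <- data.frame(
    site_id = rep(sites, times = spec$n_samples),
    sample_id = rep(samples, each = spec$n_sites),
    depth = as.vector(depth), alt_count = as.vector(alt),
    stringsAsFactors = FALSE)
  site_counts$vaf <- ifelse(site_counts$depth > 0,
                            site_counts$alt_count / site_counts$depth, 0)

  truth <- data.frame(site_id = rep(sites, times = spec$n_samples),
                      sample_id = rep(samples, each = spec$n_sites),
                      stringsAsFactors = FALSE)[as.vector(edited), , drop = FALSE]
  rownames(truth) <- NULL

  pileup_lines <- lapply(seq_along(samples), function(j) {
    vapply(seq_along(sites), function(i) {
      d <- depth[i, j]; a <- alt[i, j]
      bases <- paste0(strrep(".", d - a), strrep("T", a))
      quals <- strrep("I", d)
      sprintf("L1\t%d\tC\t%d\t%s\t%s", i * 100L, d, bases, quals)
    }, character(1L))
  })
  names(pileup_lines) <- samples

  # UMI read families: true molecules, per-base sequencing errors, plus
  # one-base-off UMI variants that Hamming clustering must reabsorb
  umis <- .random_umis(spec$n_molecules, spec$umi_length)
  mol_seq <- .random_dna(spec$n_molecules, 30L)
  reads <- list()
  rid <- 0L
  for (i in seq_len(spec$n_molecules)) {
    nr <- max(1L, rpois(1L, spec$reads_per_molecule))
    for (k in seq_len(nr)) {
      rid <- rid + 1L
      reads[[rid]] <- data.frame(
        read_id = sprintf("r%05d", rid),
        umi = .mutate_dna(umis[i], ifelse(runif(1) < spec$umi_error_rate, 1L, 0L)),
        sequence = .mutate_dna(mol_seq[i], rbinom(1L, 30L, spec$seq_error_rate)),
        stringsAsFactors = FALSE)
    }
  }
  umi_reads <- do.call(rbind, reads)

  barcodes <- t(edited)
  list(site_counts = site_counts, truth = truth, pileup_lines = pileup_lines,
       umi_reads = umi_reads, umi_truth_molecules = spec$n_molecules,
       barcodes = barcodes, spec = spec)
}

#' Write a generated fixture to a directory
#'
#' Emits `<sample>.pileup` files, `site_counts.tsv`, `truth.tsv`,
#' `umi_reads.tsv` and `barcodes.tsv`.
#'
#' @param fixture Output of [generate_fixture()].
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(fixture$pileup_lines)) {
    writeLines(fixture$pileup_lines[[s]], file.path(dir, paste0(s, ".pileup")))
  }
  write.table(fixture$site_counts, file.path(dir, "site_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fixture$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fixture$umi_reads, file.path(dir, "umi_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_barcode_tsv(fixture$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1L))
}

## n distinct UMIs pairwise Hamming distance > 4 apart (rejection sampling):
## even after one-base sequencing errors on two different molecules' tags the
## variants stay more than 2 apart, so true molecules never merge
.random_umis <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- .random_dna(1L, len)
    if (length(out) == 0L || min(hamming_matrix(c(out, cand))[length(out) + 1L,
                                                              seq_along(out)]) > 4L) {
      out <- c(out, cand)
    }
  }
  out
}

.mutate_dna <- function(s, n_mut) {
  if (n_mut == 0L) return(s)
  chars <- strsplit(s, "")[[1L]]
  pos <- sample(length(chars), min(n_mut, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}
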