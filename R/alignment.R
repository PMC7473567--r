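#' Construct a haplotype alignment object
#'
#' The central in-memory container for multi-sample consensus sequences:
#' equal-length nucleotide strings with sample and host labels, the sorted
#' 1-based coordinates of polymorphic columns, and the per-column alleles
#' at those coordinates.  Columns containing gaps, `N`, or other ambiguity
#' characters are excluded both from `variant_positions` and from the
#' usable length used as the denominator of per-site diversity statistics.
#'
#' @param sequences character vector of equal-length nucleotide strings.
#' @param sample_ids sample labels; defaults to `seq1..seqN` or the names
#'   of `sequences`.
#' @param host_ids host label per sample; defaults to `sample_ids`
#'   (one symbiont genome per host).
#' @return an object of class `haplotype_alignment` with fields
#'   `sample_ids`, `host_ids`, `sequences`, `variant_positions`,
#'   `variant_alleles` (samples x variant sites character matrix),
#'   `genome_length`, and `usable_length`.
#' @export
haplotype_alignment <- function(sequences, sample_ids = NULL, host_ids = NULL) {
  if (length(sequences) < 1L) stop("alignment needs at least one sequence")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")")
  L <- widths[1]
  if (is.null(sample_ids)) {
    sample_ids <- names(sequences)
    if (is.null(sample_ids)) sample_ids <- paste0("seq", seq_along(sequences))
  }
  if (is.null(host_ids)) host_ids <- sample_ids
  names(sequences) <- NULL

  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  good <- colSums(!(mat == "A" | mat == "C" | mat == "G" | mat == "T")) == 0L
  nvar <- apply(mat[, good, drop = FALSE], 2, function(x) length(unique(x)))
  vpos <- which(good)[nvar > 1L]

  structure(list(
    sample_ids = as.character(sample_ids),
    host_ids = as.character(host_ids),
    sequences = sequences,
    variant_positions = as.integer(vpos),
    variant_alleles = mat[, vpos, drop = FALSE],
    genome_length = as.integer(L),
    usable_length = as.integer(sum(good))
  ), class = "haplotype_alignment")
}

# Compact constructor used by the simulators: variant columns only.
compact_alignment <- function(variant_positions, variant_alleles, genome_length,
                              sample_ids = NULL, host_ids = NULL,
                              sequences = NULL) {
  n <- nrow(variant_alleles)
  if (is.null(sample_ids)) sample_ids <- paste0("seq", seq_len(n))
  if (is.null(host_ids)) host_ids <- sample_ids
  structure(list(
    sample_ids = as.character(sample_ids),
    host_ids = as.character(host_ids),
    sequences = sequences,
    variant_positions = as.integer(variant_positions),
    variant_alleles = variant_alleles,
    genome_length = as.integer(genome_length),
    usable_length = as.integer(genome_length)
  ), class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype alignment:", length(x$sample_ids), "samples,",
      x$genome_length, "bp (", x$usable_length, "usable ),",
      length(x$variant_positions), "variant sites\n")
  invisible(x)
}

n_samples <- function(aln) length(aln$sample_ids)

#' Read a multi-sample FASTA alignment
#'
#' Sequences are upper-cased, gap characters preserved, and polymorphic
#' columns computed over columns free of gaps and ambiguity codes.
#'
#' @param path FASTA file with one record per sample.
#' @param host_map optional named character vector mapping sample ids to
#'   host labels.
#' @return a [haplotype_alignment()].
#' @export
read_fasta_alignment <- function(path, host_map = NULL) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) stop("format error reading FASTA '",
                                            path, "': ", conditionMessage(e)))
  if (length(seqs) == 0L) stop("format error: empty FASTA file '", path, "'")
  ids <- names(seqs)
  hosts <- if (!is.null(host_map)) unname(host_map[ids]) else NULL
  haplotype_alignment(as.character(seqs), sample_ids = ids, host_ids = hosts)
}

#' Write a haplotype alignment as FASTA (80-column wrapped)
#'
#' @param aln a [haplotype_alignment()] carrying full sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  if (is.null(aln$sequences))
    stop("alignment holds variant columns only; full sequences are required")
  x <- Biostrings::BStringSet(aln$sequences)
  names(x) <- aln$sample_ids
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
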