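#' Parse 6-column samtools pileup text
#'
#' Decodes the base-call string of each column: `.`/`,` become the
#' reference base, read-start tokens (`^` plus the following
#' mapping-quality character) and read-end tokens (`$`) are consumed, and
#' `+n`/`-n` indel tokens are consumed with the event count recorded per
#' column for downstream indel-proximity filtering.  Deleted bases (`*`)
#' are retained as calls so that depth accounting matches samtools.
#'
#' @param path 6-column pileup file (chrom, pos, ref, depth, calls, quals).
#' @return data frame with one row per column: `chrom`, `position`,
#'   `ref_base`, `depth`, `base_calls` (decoded, one character per read),
#'   `base_qualities`, and `n_indel_events`.
#' @export
parse_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("format error: empty pileup file '", path, "'")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  # tolerate space-separated fixtures
  if (length(parts[[1]]) < 6L) parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(parts, length, 1L) < 6L)
  if (length(bad))
    stop("parse error at pileup line ", bad[1], ": expected 6 columns")
  m <- do.call(rbind, lapply(parts, `[`, 1:6))
  ref <- toupper(m[, 3])
  dec <- tryCatch(cpp_decode_pileup(m[, 5], ref), error = function(e)
    stop("parse error in pileup '", path, "': ", conditionMessage(e)))
  depth <- as.integer(m[, 4])
  # samtools writes "* *" placeholders at zero-depth columns
  empty <- depth == 0L & m[, 5] == "*"
  dec$decoded[empty] <- ""
  m[empty, 6] <- ""
  ncall <- nchar(dec$decoded)
  if (any(ncall != depth)) {
    i <- which(ncall != depth)[1]
    stop("parse error at pileup line ", i, ": depth ", depth[i],
         " does not match ", ncall[i], " decoded base calls")
  }
  nq <- nchar(m[, 6])
  if (any(nq != ncall)) {
    i <- which(nq != ncall)[1]
    stop("parse error at pileup line ", i, ": quality string length ", nq[i],
         " does not match ", ncall[i], " decoded base calls")
  }
  data.frame(chrom = m[, 1], position = as.integer(m[, 2]), ref_base = ref,
             depth = depth, base_calls = dec$decoded, base_qualities = m[, 6],
             n_indel_events = dec$n_indel, stringsAsFactors = FALSE)
}

#' Serialize pileup columns back to 6-column text
#'
#' Inverse of [parse_pileup()] up to pileup punctuation: decoded calls are
#' written with reference-matching bases as `.`, so depth and per-base
#' counts round-trip exactly.
#'
#' @param columns data frame as returned by [parse_pileup()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(columns, path) {
  calls <- mapply(function(b, r) {
    ch <- strsplit(b, "", fixed = TRUE)[[1]]
    paste(ifelse(ch == r, ".", ch), collapse = "")
  }, columns$base_calls, columns$ref_base, USE.NAMES = FALSE)
  writeLines(paste(columns$chrom, columns$position, columns$ref_base,
                   columns$depth, ifelse(nzchar(calls), calls, "*"),
                   ifelse(nzchar(columns$base_qualities),
                          columns$base_qualities, "*"),
                   sep = "\t"), path)
  invisible(path)
}
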