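#' Construct site records for threshold filtering
#'
#' A site record carries the per-site quantities the consensus-genotype
#' filters act on: the quality/depth ratio (`QD`), the phred-scaled
#' Fisher's strand bias (`FS`), the nominal genotype quality (`GQ`), and
#' the count of mapping-quality-zero reads (`MQ0`).
#'
#' @param position 1-based coordinates.
#' @param ref_allele,alt_alleles nucleotide strings; multiple alternates
#'   comma-separated within one string.
#' @param quality_by_depth,fisher_strand,genotype_quality,mq0_reads
#'   numeric filter quantities (NA = missing).
#' @return data frame of class `site_records` (one row per site) with an
#'   `allele_number` column giving 1 + the number of alternate alleles.
#' @export
site_records <- function(position, ref_allele, alt_alleles,
                         quality_by_depth = NA_real_, fisher_strand = NA_real_,
                         genotype_quality = NA_real_, mq0_reads = NA_integer_) {
  position <- as.integer(position)
  if (any(position < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(mq0_reads < 0L, na.rm = TRUE)) stop("mq0_reads must be >= 0")
  if (any(genotype_quality < 0, na.rm = TRUE))
    stop("genotype_quality must be >= 0")
  df <- data.frame(position = position,
                   ref_allele = toupper(as.character(ref_allele)),
                   alt_alleles = toupper(as.character(alt_alleles)),
                   quality_by_depth = as.numeric(quality_by_depth),
                   fisher_strand = as.numeric(fisher_strand),
                   genotype_quality = as.numeric(genotype_quality),
                   mq0_reads = as.integer(mq0_reads),
                   stringsAsFactors = FALSE)
  df$allele_number <- 1L + ifelse(df$alt_alleles %in% c("", "."), 0L,
                                  lengths(strsplit(df$alt_alleles, ",",
                                                   fixed = TRUE)))
  class(df) <- c("site_records", "data.frame")
  df
}

#' Read site records from a VCF file
#'
#' Only the INFO keys `QD`, `FS`, `MQ0` and the FORMAT key `GQ` are
#' consumed; unknown INFO keys are ignored.  With multiple samples the
#' per-record genotype quality is the minimum across samples.
#'
#' @param path VCF v4.x file (plain text or gzipped).
#' @return [site_records()] data frame.
#' @export
read_site_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key, as.numeric = TRUE)
    if (is.null(x)) rep(NA_real_, nrow(fix)) else as.numeric(x)
  }
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  gq_min <- if (is.null(gq)) rep(NA_real_, nrow(fix)) else
    apply(as.matrix(gq), 1, function(x)
      if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  site_records(position = as.integer(fix[, "POS"]),
               ref_allele = fix[, "REF"], alt_alleles = fix[, "ALT"],
               quality_by_depth = info_num("QD"),
               fisher_strand = info_num("FS"),
               genotype_quality = unname(gq_min),
               mq0_reads = as.integer(info_num("MQ0")))
}

#' Apply consensus-site threshold filters
#'
#' Two filter modes are provided.  `genotyping` keeps sites with a
#' quality/depth ratio of at least 2, Fisher's strand value at most 60,
#' nominal genotype quality at least 20, and at most 5 mapping-quality-zero
#' reads.  `fourgamete` keeps biallelic single-nucleotide sites with
#' genotype quality at least 10 (the input to four-gamete analyses).
#' Records missing a required quantity are dropped and counted in the
#' `n_dropped_missing` attribute, with one summary warning.
#'
#' Filtering is idempotent: applying the same mode twice equals applying
#' it once.
#'
#' @param records [site_records()] data frame.
#' @param mode `"genotyping"` or `"fourgamete"`.
#' @return the surviving records, with attribute `n_dropped_missing`.
#' @export
filter_consensus_sites <- function(records,
                                   mode = c("genotyping", "fourgamete")) {
  mode <- match.arg(mode)
  if (mode == "genotyping") {
    need <- cbind(records$quality_by_depth, records$fisher_strand,
                  records$genotype_quality, records$mq0_reads)
    missing <- apply(is.na(need), 1, any)
    keep <- !missing &
      records$quality_by_depth >= 2 &
      records$fisher_strand <= 60 &
      records$genotype_quality >= 20 &
      records$mq0_reads <= 5
  } else {
    missing <- is.na(records$genotype_quality) | is.na(records$alt_alleles) |
      records$alt_alleles %in% c("", ".")
    biallelic_snv <- !missing &
      records$allele_number == 2L &
      nchar(records$ref_allele) == 1L &
      nchar(records$alt_alleles) == 1L
    keep <- biallelic_snv & records$genotype_quality >= 10
  }
  keep[is.na(keep)] <- FALSE
  if (any(missing))
    warning(sum(missing), " record(s) dropped for missing filter fields")
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped_missing") <- sum(missing)
  out
}

#' Write a filtered-site report as TSV
#'
#' @param records [site_records()] data frame (typically the output of
#'   [filter_consensus_sites()]).
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(records, path) {
  write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
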