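# Alignment-level population-genetic summaries: pi, Watterson's theta,
# Tajima's D, folded AFS, distance-binned four-gamete profiles, Hudson Fst.

# 0/1 minor/major coding and counts for biallelic columns
biallelic_sites <- function(aln) {
  m <- aln$variant_alleles
  n <- nrow(m)
  keep <- logical(ncol(m))
  minor <- integer(ncol(m))
  code <- matrix(0L, n, ncol(m))
  for (j in seq_len(ncol(m))) {
    tab <- sort(table(m[, j]), decreasing = TRUE)
    if (length(tab) != 2L) next
    keep[j] <- TRUE
    minor[j] <- as.integer(tab[2L])
    code[, j] <- as.integer(m[, j] == names(tab)[2L])
  }
  list(positions = aln$variant_positions[keep],
       code = code[, keep, drop = FALSE],
       minor_count = minor[keep],
       n_excluded = sum(!keep))
}

# total (not per-site) mean pairwise difference count
pi_total <- function(aln) {
  b <- biallelic_sites(aln)
  n <- n_samples(aln)
  cnt <- colSums(b$code)
  # multi-allelic columns still contribute differences; count them directly
  extra <- 0
  if (b$n_excluded > 0) {
    multi <- setdiff(seq_along(aln$variant_positions),
                     match(b$positions, aln$variant_positions))
    for (j in multi) {
      tab <- table(aln$variant_alleles[, j])
      extra <- extra + (choose(n, 2) - sum(choose(tab, 2)))
    }
  }
  (sum(cnt * (n - cnt)) + extra) / choose(n, 2)
}

#' Per-site nucleotide diversity (pi)
#'
#' Mean pairwise difference count over all unordered sample pairs, divided
#' by the usable alignment length (genome length minus columns excluded
#' for gaps or ambiguity codes).
#'
#' @param aln a [haplotype_alignment()].
#' @return per-site pi.
#' @export
nucleotide_diversity <- function(aln) {
  if (n_samples(aln) < 2) stop("need at least two samples")
  pi_total(aln) / aln$usable_length
}

#' Per-site Watterson's theta
#'
#' `S / (a_{n-1} * L)` with `a_{n-1} = sum(1/i, i = 1..n-1)`, `S` the
#' number of segregating sites and `L` the usable length.
#'
#' @param aln a [haplotype_alignment()].
#' @return per-site Watterson estimate.
#' @export
watterson_theta <- function(aln) {
  n <- n_samples(aln)
  if (n < 2) stop("need at least two samples")
  S <- length(aln$variant_positions)
  S / (sum(1 / seq_len(n - 1)) * aln$usable_length)
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and
#' segregating-sites estimators of theta, with the standard variance
#' constants.  With no segregating sites the statistic is undefined and
#' `NA` is returned with attribute `status = "no_segregating_sites"`.
#'
#' @param aln a [haplotype_alignment()].
#' @return the D statistic (attribute `status` is `"ok"` or
#'   `"no_segregating_sites"`).
#' @export
tajimas_d <- function(aln) {
  n <- n_samples(aln)
  if (n < 2) stop("need at least two samples")
  S <- length(aln$variant_positions)
  if (S == 0L)
    return(structure(NA_real_, status = "no_segregating_sites"))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  d <- pi_total(aln) - S / a1
  structure(d / sqrt(e1 * S + e2 * S * (S - 1)), status = "ok")
}

#' Folded allele frequency spectrum
#'
#' Counts of biallelic variant sites by minor-allele count `1..floor(n/2)`
#' (ties at `n/2` fall in the `n/2` class).  Non-biallelic variant columns
#' are excluded and counted.
#'
#' @param aln a [haplotype_alignment()].
#' @return list with `counts` (named vector), `n_samples`,
#'   `n_excluded_sites`.
#' @export
folded_afs <- function(aln) {
  n <- n_samples(aln)
  b <- biallelic_sites(aln)
  classes <- seq_len(floor(n / 2))
  counts <- setNames(integer(length(classes)), classes)
  tab <- table(b$minor_count)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, n_samples = n, n_excluded_sites = b$n_excluded)
}

# half-open distance bins (0,10], (10,1e2], ..., (1e5,1e6]
f4_breaks <- c(0, 10, 1e2, 1e3, 1e4, 1e5, 1e6)

#' Distance-binned four-gamete profile
#'
#' For every unordered pair of non-singleton biallelic sites (minor allele
#' count >= 2), records whether all four haplotypic allele combinations
#' occur, and bins pairs by inter-site distance into half-open bins
#' bounded at 10, 1e2, 1e3, 1e4, 1e5 and 1e6 bp.  Under infinite-sites
#' mutation on a single genealogy at most three combinations can occur,
#' so a "failing" pair (all four present) is evidence of recombination
#' between the sites.
#'
#' @param aln a [haplotype_alignment()].
#' @return list with `proportions` (length 6; `NA` marks an empty bin),
#'   `n_pairs`, `n_failing`, and `n_excluded_pairs` (distance > 1e6).
#' @export
four_gamete_profile <- function(aln) {
  b <- biallelic_sites(aln)
  ns <- b$minor_count >= 2L
  pos <- b$positions[ns]
  A <- b$code[, ns, drop = FALSE]
  S <- length(pos)
  empty <- list(proportions = rep(NA_real_, 6L), n_pairs = integer(6L),
                n_failing = integer(6L), n_excluded_pairs = 0L)
  if (S < 2L) return(empty)
  Ac <- 1 - A
  all4 <- (crossprod(A) > 0) & (crossprod(Ac) > 0) &
    (crossprod(A, Ac) > 0) & (crossprod(Ac, A) > 0)
  ut <- upper.tri(all4)
  d <- abs(outer(pos, pos, "-"))[ut]
  fail <- all4[ut]
  inrange <- d <= 1e6
  bin <- findInterval(d[inrange], f4_breaks, left.open = TRUE)
  n_pairs <- tabulate(bin, nbins = 6L)
  n_fail <- tabulate(bin[fail[inrange]], nbins = 6L)
  prop <- ifelse(n_pairs > 0, n_fail / n_pairs, NA_real_)
  list(proportions = prop, n_pairs = n_pairs, n_failing = n_fail,
       n_excluded_pairs = sum(!inrange))
}

#' Summary-statistic feature vector
#'
#' The feature vector consumed by the regression-ABC fit: per-site pi,
#' per-site Watterson's theta, and the six distance-binned four-gamete
#' proportions.  Empty four-gamete bins are reported `NA` here; the model
#' imputes them to 0 with indicator features at fitting time.
#'
#' @param aln a [haplotype_alignment()].
#' @return list of class `summary_vector` with fields `pi`, `watterson`,
#'   `f4_bins`, `n_samples`, `n_sites_used`.
#' @export
summary_vector <- function(aln) {
  f4 <- four_gamete_profile(aln)
  structure(list(pi = nucleotide_diversity(aln),
                 watterson = watterson_theta(aln),
                 f4_bins = f4$proportions,
                 f4_n_pairs = f4$n_pairs,
                 n_samples = n_samples(aln),
                 n_sites_used = aln$usable_length),
            class = "summary_vector")
}

#' Write summary vectors as TSV
#'
#' Column order is the ABC feature contract: `pi`, `watterson`,
#' `f4_bin1..f4_bin6`, `n_samples`, `n_sites_used`.
#'
#' @param sv a `summary_vector` or list of them.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(sv, path) {
  if (inherits(sv, "summary_vector")) sv <- list(sv)
  rows <- lapply(sv, function(s) {
    as.data.frame(c(list(pi = s$pi, watterson = s$watterson),
                    setNames(as.list(s$f4_bins), paste0("f4_bin", 1:6)),
                    list(n_samples = s$n_samples,
                         n_sites_used = s$n_sites_used)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Hudson's Fst between two host groups with bootstrap CI
#'
#' Ratio-of-averages Hudson estimator.  With per-group sample sizes the
#' within-group heterozygosity is sample-size corrected
#' (`num = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`); in
#' frequency-only mode `num = (p1-p2)^2`.  The denominator is
#' `p1(1-p2) + p2(1-p1)` in both modes.  The 95% confidence interval is a
#' percentile interval from a non-parametric bootstrap over sites.
#'
#' @param p1,p2 per-site allele frequencies in the two groups.
#' @param n1,n2 optional per-group haplotype counts (enables the
#'   sample-size correction).
#' @param n_bootstrap bootstrap replicates.
#' @param seed optional randomization seed.
#' @return list of class `fst_result`: `fst`, `ci_low`, `ci_high`,
#'   `n_bootstrap`, `n_sites`.
#' @export
fst_between_hosts <- function(p1, p2, n1 = NULL, n2 = NULL,
                              n_bootstrap = 1000L, seed = NULL) {
  ok <- !is.na(p1) & !is.na(p2)
  p1 <- p1[ok]; p2 <- p2[ok]
  if (length(p1) == 0L) stop("estimation error: no usable sites")
  if (!is.null(seed)) set.seed(seed)
  num <- (p1 - p2)^2
  if (!is.null(n1) && !is.null(n2))
    num <- num - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  est <- function(idx) {
    d <- sum(den[idx])
    if (d <= 0) return(NA_real_)
    sum(num[idx]) / d
  }
  point <- est(seq_along(p1))
  bs <- vapply(seq_len(n_bootstrap), function(i)
    est(sample.int(length(p1), replace = TRUE)), 0)
  ci <- quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(fst = point, ci_low = ci[1], ci_high = ci[2],
                 n_bootstrap = as.integer(n_bootstrap),
                 n_sites = length(p1)), class = "fst_result")
}

#' Per-site allele frequencies by host group
#'
#' Frequencies of the global minor allele of each biallelic site within
#' two host groups of an alignment, the input to [fst_between_hosts()].
#'
#' @param aln a [haplotype_alignment()] with host labels.
#' @param hosts1,hosts2 host labels defining the two groups.
#' @return list with `p1`, `p2`, `n1`, `n2`.
#' @export
host_group_freqs <- function(aln, hosts1, hosts2) {
  b <- biallelic_sites(aln)
  g1 <- aln$host_ids %in% hosts1
  g2 <- aln$host_ids %in% hosts2
  if (!any(g1) || !any(g2)) stop("empty host group")
  list(p1 = colMeans(b$code[g1, , drop = FALSE]),
       p2 = colMeans(b$code[g2, , drop = FALSE]),
       n1 = sum(g1), n2 = sum(g2))
}
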