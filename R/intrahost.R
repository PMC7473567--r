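# Within-host analyses from reads: the pileup variant caller with
# coverage, indel-proximity and binomial sequencing-error filters;
# within-host folded spectra; and the read-backed four-gamete test.

base_counts <- function(call_string) {
  ch <- strsplit(call_string, "", fixed = TRUE)[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"))
}

phred_error <- function(qual_string) {
  if (!nzchar(qual_string)) return(NA_real_)
  q <- utf8ToInt(qual_string) - 33L
  mean(10^(-q / 10))
}

#' Call within-host variants from pileup columns
#'
#' Three filters are applied in order: (1) columns whose depth falls
#' outside mean +/- 1 SD of the genome-wide depth are dropped; (2) columns
#' within `indel_window` bp of an indel-bearing column are dropped; (3) an
#' alternate allele is called when the upper-tail binomial probability of
#' observing at least `alt_count` error reads,
#' `P(X >= alt_count | depth, error_rate)`, is below `alpha`.  The
#' per-site error rate defaults to the mean phred-implied error of the
#' column's base qualities, or to `error_rate` when given.  Per-site
#' within-host diversity is `2 p (1 - p) depth / (depth - 1)` at called
#' sites, averaged over all usable sites.
#'
#' @param columns data frame from [parse_pileup()].
#' @param error_rate fixed per-base error probability; `NULL` (default)
#'   derives it per site from base qualities.
#' @param alpha per-site significance level (default 0.05).
#' @param indel_window bp on each side of an indel-bearing column to
#'   exclude (default 5).
#' @param bonferroni apply a Bonferroni correction of `alpha` across the
#'   usable columns (off by default).
#' @return list of class `withinhost_calls`: `variants` (data frame),
#'   `pi_within`, `n_usable_sites`, `n_depth_filtered`,
#'   `n_indel_filtered`, `status`.
#' @export
call_within_host_variants <- function(columns, error_rate = NULL,
                                      alpha = 0.05, indel_window = 5L,
                                      bonferroni = FALSE) {
  if (nrow(columns) == 0L) stop("no pileup columns supplied")
  mu <- mean(columns$depth)
  sdv <- sd(columns$depth)
  if (is.na(sdv)) sdv <- 0
  depth_ok <- columns$depth >= mu - sdv & columns$depth <= mu + sdv
  indel_pos <- columns$position[columns$n_indel_events > 0L]
  near_indel <- if (length(indel_pos) == 0L) rep(FALSE, nrow(columns)) else
    vapply(columns$position,
           function(p) any(abs(p - indel_pos) <= indel_window), NA)
  usable <- depth_ok & !near_indel & columns$depth >= 2L
  out_empty <- list(variants = data.frame(), pi_within = NA_real_,
                    n_usable_sites = 0L,
                    n_depth_filtered = sum(!depth_ok),
                    n_indel_filtered = sum(near_indel & depth_ok),
                    status = "all columns filtered")
  if (!any(usable)) return(structure(out_empty, class = "withinhost_calls"))

  cols <- columns[usable, , drop = FALSE]
  n_test <- nrow(cols)
  a_eff <- if (bonferroni) alpha / n_test else alpha
  vars <- vector("list", n_test)
  pi_acc <- 0
  for (i in seq_len(n_test)) {
    bc <- base_counts(cols$base_calls[i])
    ref <- cols$ref_base[i]
    altc <- bc[setdiff(names(bc), ref)]
    if (all(altc == 0L)) next
    alt <- names(altc)[which.max(altc)]
    ac <- as.integer(altc[alt])
    d <- as.integer(sum(bc))
    e <- if (!is.null(error_rate)) error_rate else
      phred_error(cols$base_qualities[i])
    if (is.na(e)) e <- 0.01
    pval <- pbinom(ac - 1L, d, e, lower.tail = FALSE)
    if (pval < a_eff && ac < d) {
      p <- ac / d
      pi_acc <- pi_acc + 2 * p * (1 - p) * d / (d - 1)
      vars[[i]] <- data.frame(position = cols$position[i], ref_allele = ref,
                              alt_allele = alt, depth = d, alt_count = ac,
                              alt_freq = p, error_prob_used = e,
                              p_value = pval)
    }
  }
  vars <- do.call(rbind, vars[!vapply(vars, is.null, NA)])
  if (is.null(vars)) vars <- data.frame()
  structure(list(variants = vars,
                 pi_within = pi_acc / n_test,
                 n_usable_sites = n_test,
                 n_depth_filtered = sum(!depth_ok),
                 n_indel_filtered = sum(near_indel & depth_ok),
                 status = "ok"),
            class = "withinhost_calls")
}

#' Folded spectrum of within-host minor allele read frequencies
#'
#' Minor frequency is `min(alt_freq, 1 - alt_freq)`; the histogram covers
#' (0, 0.5] with `n_bins` equal-width bins.
#'
#' @param variants data frame from [call_within_host_variants()].
#' @param n_bins number of bins (default 10).
#' @return list with `counts`, `breaks`, `status`.
#' @export
within_host_folded_afs <- function(variants, n_bins = 10L) {
  breaks <- seq(0, 0.5, length.out = n_bins + 1L)
  if (is.null(variants) || nrow(variants) == 0L)
    return(list(counts = integer(n_bins), breaks = breaks,
                status = "no variants"))
  f <- pmin(variants$alt_freq, 1 - variants$alt_freq)
  bin <- pmin(pmax(findInterval(f, breaks, left.open = TRUE), 1L), n_bins)
  list(counts = tabulate(bin, nbins = n_bins), breaks = breaks,
       status = "ok")
}

#' Read-backed four-gamete test on read-pair allele observations
#'
#' For every pair of sites with at least `min_total` joint observations on
#' single read pairs, tallies the four allelic configurations AB, Ab, aB,
#' ab (A/a, B/b being the two most frequent bases at each site among the
#' pair's observations) and flags the pair when every configuration's
#' proportion strictly exceeds `min_prop`.  Pairs below `min_total` are
#' reported with status `"insufficient_observations"` and never flagged.
#' Observations carrying a base matching neither allele at a site are
#' discarded and counted.
#'
#' @param observations data frame with columns `read_id`, `pos_a`,
#'   `base_a`, `pos_b`, `base_b` (one row per read pair per site pair).
#' @param min_total minimum joint observations (default 100).
#' @param min_prop minimum configuration proportion (default 0.05,
#'   strict inequality).
#' @return data frame of class `site_pair_phase`: `pos_a`, `pos_b`,
#'   counts `AB`, `Ab`, `aB`, `ab`, `total`, `all_four_flag`, `status`,
#'   `n_discarded`.
#' @export
read_pair_four_gamete <- function(observations, min_total = 100L,
                                  min_prop = 0.05) {
  need <- c("read_id", "pos_a", "base_a", "pos_b", "base_b")
  if (!all(need %in% names(observations)))
    stop("observations must have columns ", paste(need, collapse = ", "))
  key <- paste(observations$pos_a, observations$pos_b, sep = ":")
  rows <- lapply(split(observations, key), function(d) {
    pa <- d$pos_a[1]; pb <- d$pos_b[1]
    ta <- sort(table(d$base_a), decreasing = TRUE)
    tb <- sort(table(d$base_b), decreasing = TRUE)
    aA <- names(ta)[1]; aa <- if (length(ta) > 1) names(ta)[2] else NA
    bB <- names(tb)[1]; bb <- if (length(tb) > 1) names(tb)[2] else NA
    ok <- d$base_a %in% c(aA, aa) & d$base_b %in% c(bB, bb)
    n_disc <- sum(!ok)
    d <- d[ok, , drop = FALSE]
    cfg <- c(AB = sum(d$base_a == aA & d$base_b == bB),
             Ab = sum(d$base_a == aA & d$base_b != bB),
             aB = sum(d$base_a != aA & d$base_b == bB),
             ab = sum(d$base_a != aA & d$base_b != bB))
    total <- sum(cfg)
    enough <- total >= min_total
    flag <- enough && total > 0 && all(cfg / total > min_prop)
    data.frame(pos_a = pa, pos_b = pb,
               AB = cfg[["AB"]], Ab = cfg[["Ab"]], aB = cfg[["aB"]],
               ab = cfg[["ab"]], total = total, all_four_flag = flag,
               status = if (enough) "ok" else "insufficient_observations",
               n_discarded = n_disc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("site_pair_phase", "data.frame")
  out
}
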