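# shared fixture builders used across test files

# pileup columns for a two-haplotype mixture at fixed depth: each read is
# the alternate base with probability `freq`, then independent per-base
# sequencing errors are applied
make_variant_pileup <- function(n_sites, depth, freq, error_rate,
                                ref = "A", alt = "C") {
  bases <- c("A", "C", "G", "T")
  qc <- intToUtf8(min(40L, as.integer(round(-10 * log10(max(error_rate,
                                                            1e-4))))) + 33L)
  calls <- vapply(seq_len(n_sites), function(i) {
    b <- ifelse(runif(depth) < freq, alt, ref)
    err <- which(runif(depth) < error_rate)
    for (k in err) b[k] <- sample(setdiff(bases, b[k]), 1L)
    paste(b, collapse = "")
  }, "")
  data.frame(chrom = "ref", position = seq_len(n_sites), ref_base = ref,
             depth = depth, base_calls = calls,
             base_qualities = strrep(qc, depth), n_indel_events = 0L,
             stringsAsFactors = FALSE)
}

# per-replicate overall four-gamete failure proportion from the simulator
f4_failure_prop <- function(params) {
  r <- simulate_coalescent_gc(params, emit = "sites")
  f <- four_gamete_profile(r$alignment)
  if (sum(f$n_pairs) == 0) NA_real_ else sum(f$n_failing) / sum(f$n_pairs)
}
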