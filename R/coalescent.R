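#' Parameters for the gene-conversion coalescent
#'
#' @param theta population-scaled mutation rate per bp (2*Ne*mu).
#' @param rho population-scaled gene-conversion initiation rate per bp
#'   (2*Ne*r).
#' @param tract_length gene-conversion tract length in bp; tracts are
#'   truncated at the sequence end, so values larger than `genome_length`
#'   behave as a single breakpoint at the initiation site.
#' @param genome_length genome length in bp.
#' @param sample_size number of haplotypes (2..64).
#' @param seed optional randomization seed.
#' @return a `sim_params` list.
#' @export
sim_params <- function(theta, rho = 0, tract_length = 1000L,
                       genome_length = 10000L, sample_size = 10L,
                       seed = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  if (rho < 0) stop("rho must be >= 0")
  if (tract_length < 1) stop("tract_length must be >= 1")
  if (sample_size < 2) stop("sample_size must be >= 2")
  if (genome_length < 1) stop("genome_length must be >= 1")
  # infinite-sites guard: integer positions must comfortably hold E[S]
  es <- theta * genome_length * sum(1 / seq_len(max(1, sample_size - 1)))
  if (es * 10 > genome_length)
    stop("genome_length must exceed 10x the expected number of segregating ",
         "sites (", signif(es, 3), "); increase genome_length or lower theta")
  structure(list(theta = theta, rho = rho,
                 tract_length = as.integer(round(tract_length)),
                 genome_length = as.integer(genome_length),
                 sample_size = as.integer(sample_size), seed = seed),
            class = "sim_params")
}

#' Simulate a neutral coalescent sample with bacterial gene conversion
#'
#' Runs an exact ancestral-recombination-graph simulation (no sequential
#' Markov approximation, no precomputed clonal frame): lineages carry
#' ancestral material, gene conversion splits a lineage at rate rho/2 per
#' initiation site into the tract and its complement, pairs coalesce at
#' rate 1, and infinite-sites mutations fall on lineages at rate theta/2
#' per carried site, mapped to distinct integer positions.
#'
#' @param params a [sim_params()] object.
#' @param emit `"alignment"` materializes full sequences over a random
#'   reference; `"sites"` returns variant columns only (faster; used for
#'   training simulations).
#' @param event_budget abort guard on the number of ancestral-process
#'   events.
#' @return a `sim_replicate` list: `alignment` ([haplotype_alignment()]),
#'   `n_recomb_events`, `params`.
#' @export
simulate_coalescent_gc <- function(params, emit = c("alignment", "sites"),
                                   event_budget = 2e7) {
  emit <- match.arg(emit)
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$sample_size
  L <- params$genome_length
  res <- cpp_simulate_gc(n, L, params$theta, params$rho,
                         params$tract_length, event_budget)
  S <- length(res$positions)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, S, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1L), "")
  alle <- matrix(rep(anc, each = n), nrow = n)
  if (S > 0) alle[res$derived == 1L] <- rep(der, each = n)[res$derived == 1L]
  seqs <- NULL
  if (emit == "alignment") {
    ref <- sample(bases, L, replace = TRUE)
    ref[res$positions] <- anc
    seqs <- vapply(seq_len(n), function(i) {
      x <- ref
      x[res$positions] <- alle[i, ]
      paste(x, collapse = "")
    }, "")
  }
  aln <- compact_alignment(res$positions, alle, L, sequences = seqs)
  structure(list(alignment = aln,
                 n_recomb_events = res$n_recomb_events,
                 n_events = res$n_events,
                 n_skipped_mutations = res$n_skipped_mutations,
                 params = params),
            class = "sim_replicate")
}

#' Neutral expectation for the number of segregating sites
#'
#' Watterson's expectation `theta * L * sum(1/i, i = 1..n-1)`, used to
#' calibrate the simulator.
#'
#' @param params a [sim_params()] object.
#' @return expected segregating-site count.
#' @export
expected_segregating_sites <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  params$theta * params$genome_length *
    sum(1 / seq_len(params$sample_size - 1L))
}
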