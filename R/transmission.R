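#' Parameters for the host-structured transmission model
#'
#' Hosts reproduce by Wright-Fisher sampling.  Each offspring host's
#' symbiont population is founded by `bottleneck` cells drawn from its
#' parent host and instantly regrown to `n_symbionts` by multinomial
#' resampling.  With probability `horizontal_rate` per generation an
#' offspring symbiont lineage is instead acquired horizontally: it copies
#' a uniformly random symbiont from a uniformly random host of the
#' parental generation, bypassing the transmission bottleneck.  Mutations
#' accrue on lineages as Poisson counts at `mutation_rate` per genome per
#' generation and are compared by infinite-alleles difference counting.
#'
#' @param n_hosts NH, host population size (>= 2).
#' @param n_symbionts NS, symbionts per host (>= 1).
#' @param horizontal_rate H in `[0, 1]`.
#' @param mutation_rate per-genome per-generation rate; the default 2e-3
#'   corresponds to a ~1 Mb genome at ~2e-9 substitutions/bp/generation.
#' @param bottleneck symbiont cells transmitted per host offspring;
#'   defaults to `min(30, n_symbionts)`.
#' @param n_generations burn-in; defaults to the stationarity guard
#'   `10 * n_hosts * n_symbionts`.
#' @param seed optional randomization seed.
#' @return a `transmission_params` list.
#' @export
transmission_params <- function(n_hosts, n_symbionts, horizontal_rate,
                                mutation_rate = 2e-3,
                                bottleneck = min(30L, n_symbionts),
                                n_generations = 10L * n_hosts * n_symbionts,
                                seed = NULL) {
  if (n_hosts < 2) stop("n_hosts must be >= 2")
  if (n_symbionts < 1) stop("n_symbionts must be >= 1")
  if (horizontal_rate < 0 || horizontal_rate > 1)
    stop("horizontal_rate must be in [0, 1]")
  if (mutation_rate < 0) stop("mutation_rate must be >= 0")
  if (bottleneck < 1 || bottleneck > n_symbionts)
    stop("bottleneck must be in [1, n_symbionts]")
  if (n_generations < 10 * n_hosts * n_symbionts)
    stop("configuration error: n_generations (", n_generations,
         ") is below the stationarity guard 10 * NH * NS (",
         10 * n_hosts * n_symbionts, ")")
  structure(list(n_hosts = as.integer(n_hosts),
                 n_symbionts = as.integer(n_symbionts),
                 horizontal_rate = horizontal_rate,
                 mutation_rate = mutation_rate,
                 bottleneck = as.integer(bottleneck),
                 n_generations = as.integer(n_generations),
                 seed = seed),
            class = "transmission_params")
}

#' Forward-simulate the transmission model
#'
#' Each replicate is an independent forward run to stationarity; at the
#' end two symbionts are sampled from two distinct random hosts and their
#' pairwise difference count recorded, together with mean within-host and
#' between-host pairwise diversity over randomly sampled cell pairs.
#'
#' @param params a [transmission_params()] object.
#' @param n_replicates independent forward runs.
#' @param n_within_pairs,n_between_pairs cell pairs sampled per replicate
#'   for the diversity summaries.
#' @return data frame with columns `replicate`, `d_pair`, `mean_within`,
#'   `mean_between`; the parameters are attached as attribute `params`.
#' @export
simulate_transmission <- function(params, n_replicates = 100L,
                                  n_within_pairs = 200L,
                                  n_between_pairs = 200L) {
  stopifnot(inherits(params, "transmission_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  rows <- lapply(seq_len(n_replicates), function(r) {
    x <- cpp_transmission(params$n_hosts, params$n_symbionts,
                          params$horizontal_rate, params$mutation_rate,
                          params$bottleneck, params$n_generations,
                          n_within_pairs, n_between_pairs,
                          FALSE, 0L, 0L)
    data.frame(replicate = r, d_pair = x$d_pair,
               mean_within = x$mean_within, mean_between = x$mean_between)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- params
  out
}

#' Closed-form expectation of pairwise differences
#'
#' Exact expectation of the number of differences between two symbionts
#' sampled from two distinct random hosts (and, as attribute `within`,
#' from the same host), obtained by first-step analysis of the
#' two-lineage backward chain of the transmission model.  With states
#' S (same host) and D (different hosts), per-generation coalescence
#' probabilities are
#' `p_S = (1-H)^2 * a + H*(2-H) / (NH*NS)` with
#' `a = 1/B + (1 - 1/B)/NS`, and `p_D = 1/(NH*NS)`; the expected
#' coalescence times solve a 2x2 linear system and the expectation is
#' `2 * mu * T_D`.  At `H = 1` the model collapses to a panmictic
#' Wright-Fisher population of `NH * NS` symbionts (`T_D = T_S = NH*NS`).
#'
#' @param params a [transmission_params()] object.
#' @return expected between-host pairwise difference count, with
#'   attributes `within` (same-host expectation), `T_D` and `T_S`
#'   (expected coalescence times in generations).
#' @export
expected_pairwise_differences <- function(params) {
  stopifnot(inherits(params, "transmission_params"))
  NH <- params$n_hosts; NS <- params$n_symbionts
  H <- params$horizontal_rate; B <- params$bottleneck
  a <- 1 / B + (1 - 1 / B) / NS
  pS <- (1 - H)^2 * a + H * (2 - H) / (NH * NS)
  pSS <- (1 - H)^2 * (1 - a) + H * (2 - H) * (NS - 1) / (NH * NS)
  pSD <- H * (2 - H) * (1 - 1 / NH)
  pDS <- (NS - 1) / (NH * NS)
  pDD <- 1 - 1 / NH
  ## (I - P) T = 1 over transient states (S, D)
  M <- rbind(c(1 - pSS, -pSD), c(-pDS, 1 - pDD))
  Tt <- solve(M, c(1, 1))
  ev <- 2 * params$mutation_rate * Tt[2]
  structure(ev, within = 2 * params$mutation_rate * Tt[1],
            T_S = Tt[1], T_D = Tt[2])
}

#' Compare forward simulation with the closed-form expectation
#'
#' @param params a [transmission_params()] object.
#' @param n_replicates forward replicates.
#' @return list with `observed_mean`, `expected`, `n_replicates`, and
#'   `abs_deviation`.
#' @export
pairwise_diff_check <- function(params, n_replicates = 100L) {
  sim <- simulate_transmission(params, n_replicates = n_replicates,
                               n_within_pairs = 0L, n_between_pairs = 0L)
  expd <- as.numeric(expected_pairwise_differences(params))
  obs <- mean(sim$d_pair)
  list(observed_mean = obs, expected = expd, n_replicates = n_replicates,
       abs_deviation = abs(obs - expd))
}
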