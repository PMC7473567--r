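# End-to-end orchestration: observed alignment -> summary statistics ->
# per-sample-size random-forest model (training if absent, cached) ->
# estimates -> r/m report; plus the validation command that reruns the
# model-agreement, calibration, recombination-signal and intrahost
# property suites.

resolve_config <- function(config, defaults) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  out <- utils::modifyList(defaults, config)
  out
}

log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the fit pipeline on an observed alignment
#'
#' Reads the alignment, computes the summary-statistic vector, obtains a
#' random-forest model trained at the observed sample size (training sets
#' are cached by a hash of the prior specification, sample size, genome
#' length, simulation count and seed), produces theta and rho*l estimates
#' with confidence intervals, converts to r/m, and writes a TSV report, a
#' resolved-config JSON and a log beside the outputs.
#'
#' @param config list or JSON path with fields `fasta` (path, required),
#'   `out_dir` (default `"symbiocoal_fit"`), `n_sims` (default 2000),
#'   `genome_length` (training genome length, default 20000), `n_trees`
#'   (default 500), `seed` (default 1), `train` (set `FALSE` to forbid
#'   training), `cache_dir` (default `file.path(out_dir, "cache")`),
#'   `theta_recombinant`/`theta_genome` (optional r/m inputs; both default
#'   to the estimated theta, in which case r/m equals rho*l).
#' @return list with `summary`, `fit`, `rate`, `report` (data frame), and
#'   `report_path`.
#' @export
run_fit_pipeline <- function(config) {
  cfg <- resolve_config(config, list(
    out_dir = "symbiocoal_fit", n_sims = 2000L, genome_length = 20000L,
    n_trees = 500L, seed = 1L, train = TRUE, cache_dir = NULL))
  if (is.null(cfg$fasta)) stop("config field 'fasta' is required")
  if (!file.exists(cfg$fasta)) stop("input path not found: ", cfg$fasta)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(cfg$cache_dir)) cfg$cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cfg$cache_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))

  log_line(logf, "io", paste("reading", cfg$fasta))
  aln <- read_fasta_alignment(cfg$fasta)
  sv <- summary_vector(aln)
  log_line(logf, "sumstats",
           sprintf("n=%d, S=%d, pi=%.3g, watterson=%.3g (seed %d)",
                   sv$n_samples, length(aln$variant_positions), sv$pi,
                   sv$watterson, cfg$seed))

  key <- paste("prior-default", sv$n_samples, cfg$genome_length, cfg$n_sims,
               cfg$seed, sep = "_")
  cache <- file.path(cfg$cache_dir, paste0("model_", key, ".rds"))
  if (file.exists(cache)) {
    log_line(logf, "train", paste("cached model", cache))
    model <- readRDS(cache)
  } else {
    if (!isTRUE(cfg$train))
      stop("no trained model for sample size ", sv$n_samples,
           " and training is disabled; enable `train` or supply a cache")
    log_line(logf, "train", sprintf("simulating %d training sets at n=%d",
                                    cfg$n_sims, sv$n_samples))
    train <- build_training_set(prior_spec(), cfg$n_sims,
                                sample_size = sv$n_samples,
                                genome_length = cfg$genome_length,
                                seed = cfg$seed)
    model <- fit_rf(train, n_trees = cfg$n_trees, seed = cfg$seed + 1L)
    saveRDS(model, cache)
  }

  fit <- estimate(model, sv)
  th_rec <- if (!is.null(cfg$theta_recombinant)) cfg$theta_recombinant else
    fit$theta_hat
  th_gen <- if (!is.null(cfg$theta_genome)) cfg$theta_genome else
    fit$theta_hat
  rate <- r_over_m(fit$rho_l_hat, th_rec, th_gen)
  log_line(logf, "fit", sprintf(
    "theta_hat=%.4g, log10(rho*l)=%.3f, rho*l=%.4g, r/m=%.4g",
    fit$theta_hat, fit$log10_rho_l_hat, fit$rho_l_hat, rate$r_over_m))

  report <- data.frame(
    n_samples = sv$n_samples, pi = sv$pi, watterson = sv$watterson,
    rf_theta = fit$theta_hat, log10_rho_l = fit$log10_rho_l_hat,
    log10_rho_l_lower = fit$ci$lower[2], log10_rho_l_upper = fit$ci$upper[2],
    rho_l = fit$rho_l_hat, r_over_m = rate$r_over_m,
    oob_theta = unname(fit$oob_scores["theta"]),
    oob_log10_rho_l = unname(fit$oob_scores["log10_rho_l"]))
  report_path <- file.path(cfg$out_dir, "fit_report.tsv")
  write.table(report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cfg, file.path(cfg$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, null = "null")
  list(summary = sv, fit = fit, rate = rate, report = report,
       report_path = report_path)
}

#' Run the validation suites
#'
#' Executes desk-scale versions of the package's property checks and
#' emits a pass/fail table: agreement between the transmission model's
#' forward simulation and its closed-form expectation over a parameter
#' grid, coalescent calibration against the Watterson expectation, the
#' recombination four-gamete signal (zero at rho = 0, increasing in rho),
#' and intrahost caller false-positive control.
#'
#' @param config list or JSON path; fields `seed` (default 1), `out_dir`
#'   (optional: write `validation_report.tsv` there),
#'   `n_replicates_model` (default 100), `n_replicates_cal` (default 300),
#'   `expectation_offset` (harness hook: a deliberate perturbation added
#'   to the closed-form expectation; nonzero values must flag failure).
#' @return data frame with columns `check`, `statistic`, `value`,
#'   `threshold`, `pass`.
#' @export
run_validation <- function(config = list()) {
  cfg <- resolve_config(config, list(
    seed = 1L, out_dir = NULL, n_replicates_model = 100L,
    n_replicates_cal = 300L, expectation_offset = 0))
  set.seed(cfg$seed)
  rows <- list()
  add <- function(check, stat, value, threshold, pass)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, statistic = stat, value = value,
      threshold = threshold, pass = pass)

  # model agreement grid (S7-style check)
  grid <- transmission_grid()
  devs <- vapply(seq_len(nrow(grid)), function(i) {
    p <- transmission_params(grid$n_hosts[i], grid$n_symbionts[i],
                             grid$horizontal_rate[i],
                             seed = cfg$seed + i)
    chk <- pairwise_diff_check(p, n_replicates = cfg$n_replicates_model)
    abs(chk$observed_mean - (chk$expected + cfg$expectation_offset))
  }, 0)
  add("model_agreement", "max_abs_deviation", max(devs), 2,
      max(devs) < 2)

  # coalescent calibration: n = 2 pairwise segregating sites
  set.seed(cfg$seed + 100)
  p2 <- sim_params(theta = 1e-3, rho = 0, genome_length = 10000L,
                   sample_size = 2L)
  S <- vapply(seq_len(cfg$n_replicates_cal), function(i)
    length(simulate_coalescent_gc(p2, emit = "sites")$alignment$
             variant_positions), 0)
  se <- sd(S) / sqrt(length(S))
  dev <- abs(mean(S) - expected_segregating_sites(p2))
  add("coalescent_calibration", "deviation_from_expectation", dev, 3 * se,
      dev <= 3 * se)

  # four-gamete signal: exact zero at rho = 0, increasing in rho
  set.seed(cfg$seed + 200)
  f4mean <- function(rho, reps = 50) {
    mean(vapply(seq_len(reps), function(i) {
      r <- simulate_coalescent_gc(
        sim_params(theta = 2e-3, rho = rho, tract_length = 1000L,
                   genome_length = 10000L, sample_size = 10L),
        emit = "sites")
      f4 <- four_gamete_profile(r$alignment)
      if (sum(f4$n_pairs) == 0) NA_real_ else
        sum(f4$n_failing) / sum(f4$n_pairs)
    }, 0), na.rm = TRUE)
  }
  z <- f4mean(0)
  add("fourgamete_rho0", "mean_failure_proportion", z, 0, z == 0)
  lo <- f4mean(1e-5); hi <- f4mean(1e-3)
  add("fourgamete_monotone", "increase_lo_to_hi", hi - lo, 0, hi > lo)

  # intrahost false-positive control on error-only columns
  set.seed(cfg$seed + 300)
  pu <- error_only_pileup(n_sites = 2000L, depth = 100L, error_rate = 0.01)
  calls <- call_within_host_variants(pu, error_rate = 0.01, alpha = 0.05)
  fp <- nrow(calls$variants) / calls$n_usable_sites
  add("intrahost_fp_control", "called_fraction", fp, 0.05, fp <= 0.05)

  out <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(out, file.path(cfg$out_dir, "validation_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Desk-scale parameter grid for the model-agreement check
#'
#' Eight host-number / symbiont-number / horizontal-rate combinations
#' spanning near-strict vertical (H = 0) through mixed (H = 0.1, 0.5) to
#' fully horizontal (H = 1) transmission, with expected pairwise
#' differences ranging from well below one to about six.
#'
#' @return data frame with columns `n_hosts`, `n_symbionts`,
#'   `horizontal_rate`.
#' @export
transmission_grid <- function() {
  data.frame(
    n_hosts = c(30L, 30L, 30L, 60L, 60L, 60L, 100L, 150L),
    n_symbionts = c(5L, 5L, 10L, 5L, 10L, 10L, 10L, 10L),
    horizontal_rate = c(0, 1, 0.1, 0.1, 0, 1, 0.5, 1))
}

# constant-depth pileup columns whose alternate calls are pure sequencing
# error; used by the validation suite and tests
error_only_pileup <- function(n_sites, depth, error_rate,
                              ref = c("A", "C", "G", "T")) {
  refv <- sample(ref, n_sites, replace = TRUE)
  q <- min(40L, as.integer(round(-10 * log10(max(error_rate, 1e-4)))))
  qc <- intToUtf8(q + 33L)
  bases <- c("A", "C", "G", "T")
  calls <- vapply(seq_len(n_sites), function(i) {
    b <- rep(refv[i], depth)
    err <- which(runif(depth) < error_rate)
    for (k in err) b[k] <- sample(setdiff(bases, b[k]), 1L)
    paste(b, collapse = "")
  }, "")
  data.frame(chrom = "ref", position = seq_len(n_sites), ref_base = refv,
             depth = depth, base_calls = calls,
             base_qualities = strrep(qc, depth), n_indel_events = 0L,
             stringsAsFactors = FALSE)
}
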