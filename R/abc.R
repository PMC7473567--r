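# Regression-ABC engine: prior sampling, training-set construction from
# the gene-conversion coalescent, random-forest fits of theta and
# log10(rho*l) on the summary-statistic features, infinitesimal-jackknife
# confidence intervals, and conversion to r/m.

#' Prior specification for the ABC fit
#'
#' Defaults: theta log-uniform on (3e-5, 1e-2), rho log-uniform on
#' (1e-6, 1e-2), tract length uniform on (1, 1e5) bp.
#'
#' @param theta_bounds,rho_bounds,tract_bounds lower/upper bounds.
#' @return a `prior_spec` list.
#' @export
prior_spec <- function(theta_bounds = c(3e-5, 1e-2),
                       rho_bounds = c(1e-6, 1e-2),
                       tract_bounds = c(1, 1e5)) {
  chk <- function(b, nm) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stop(nm, " bounds must be positive with lower < upper")
  }
  chk(theta_bounds, "theta"); chk(rho_bounds, "rho"); chk(tract_bounds, "tract")
  structure(list(theta_bounds = theta_bounds, rho_bounds = rho_bounds,
                 tract_bounds = tract_bounds), class = "prior_spec")
}

#' Draw simulation parameters from the priors
#'
#' theta and rho are log-uniform within their bounds; the tract length is
#' uniform, rounded to integer bp.
#'
#' @param spec a [prior_spec()].
#' @param n_draws number of draws.
#' @param sample_size,genome_length attached to each draw.
#' @param seed optional randomization seed.
#' @return list of [sim_params()] objects.
#' @export
sample_priors <- function(spec, n_draws, sample_size = 10L,
                          genome_length = 20000L, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  logu <- function(b, n) exp(runif(n, log(b[1]), log(b[2])))
  th <- logu(spec$theta_bounds, n_draws)
  rh <- logu(spec$rho_bounds, n_draws)
  tr <- pmax(1L, as.integer(round(runif(n_draws, spec$tract_bounds[1],
                                        spec$tract_bounds[2]))))
  lapply(seq_len(n_draws), function(i)
    sim_params(theta = th[i], rho = rh[i], tract_length = tr[i],
               genome_length = genome_length, sample_size = sample_size))
}

# feature matrix row from a summary vector: f4 NAs imputed to 0 with
# indicator columns appended
sv_features <- function(sv) {
  f4 <- sv$f4_bins
  miss <- as.numeric(is.na(f4))
  f4[is.na(f4)] <- 0
  c(pi = sv$pi, watterson = sv$watterson,
    setNames(f4, paste0("f4_bin", 1:6)),
    setNames(miss, paste0("f4_miss", 1:6)))
}

#' Build an ABC training set
#'
#' Draws parameters from the priors, simulates each with the
#' gene-conversion coalescent, and computes the summary-statistic feature
#' row and true targets (theta, log10(rho*l), l).  Degenerate replicates
#' (no segregating sites) are retained with zero features and counted.
#'
#' @param spec a [prior_spec()].
#' @param n_sims number of simulations (>= 100).
#' @param sample_size haplotypes per simulation.
#' @param genome_length bp per simulation.
#' @param seed optional randomization seed.
#' @return list of class `training_set`: `features` (matrix), `targets`
#'   (data frame with `theta`, `log10_rho_l`, `tract_length`),
#'   `sample_size`, `n_simulations`, `n_degenerate`.
#' @export
build_training_set <- function(spec, n_sims, sample_size = 10L,
                               genome_length = 20000L, seed = NULL) {
  if (n_sims < 100) stop("need at least 100 training simulations")
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_priors(spec, n_sims, sample_size, genome_length)
  feats <- matrix(NA_real_, n_sims, 14)
  tg <- data.frame(theta = NA_real_, log10_rho_l = NA_real_,
                   tract_length = NA_real_)[rep(1, n_sims), ]
  ndeg <- 0L
  for (i in seq_len(n_sims)) {
    rep_i <- tryCatch(simulate_coalescent_gc(draws[[i]], emit = "sites"),
                      error = function(e)
                        stop("simulation failed for draw ", i, " (theta=",
                             signif(draws[[i]]$theta, 3), ", rho=",
                             signif(draws[[i]]$rho, 3), ", tract=",
                             draws[[i]]$tract_length, "): ",
                             conditionMessage(e)))
    sv <- summary_vector(rep_i$alignment)
    if (length(rep_i$alignment$variant_positions) == 0L) ndeg <- ndeg + 1L
    feats[i, ] <- sv_features(sv)
    tg$theta[i] <- draws[[i]]$theta
    tg$log10_rho_l[i] <- log10(draws[[i]]$rho * draws[[i]]$tract_length)
    tg$tract_length[i] <- draws[[i]]$tract_length
  }
  colnames(feats) <- names(sv_features(summary_vector(fixture_F1())))
  rownames(tg) <- NULL
  structure(list(features = feats, targets = tg,
                 sample_size = as.integer(sample_size),
                 genome_length = as.integer(genome_length),
                 n_simulations = as.integer(n_sims),
                 n_degenerate = ndeg),
            class = "training_set")
}

#' Fit the random-forest regressions
#'
#' One regression forest per target: theta on the natural scale and
#' log10(rho*l).  Out-of-bag R-squared scores are computed during
#' training.  Inbag counts and per-tree predictions are retained so that
#' [estimate()] can compute infinitesimal-jackknife confidence intervals.
#'
#' @param train a [build_training_set()] result.
#' @param n_trees trees per forest (default 500).
#' @param seed optional randomization seed.
#' @return list of class `symbiocoal_rf` with `forest_theta`,
#'   `forest_rho_l`, `oob_scores`, `oob_predictions`, `sample_size`,
#'   `feature_names`.
#' @export
fit_rf <- function(train, n_trees = 500L, seed = NULL) {
  stopifnot(inherits(train, "training_set"))
  if (nrow(train$features) < n_trees)
    warning("fewer training rows (", nrow(train$features),
            ") than trees (", n_trees, ")")
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(train$features)
  fit1 <- function(y) {
    d <- cbind(df, .y = y)
    ranger::ranger(dependent.variable.name = ".y", data = d,
                   num.trees = n_trees, keep.inbag = TRUE,
                   seed = sample.int(.Machine$integer.max, 1))
  }
  ft <- fit1(train$targets$theta)
  fr <- fit1(train$targets$log10_rho_l)
  structure(list(forest_theta = ft, forest_rho_l = fr,
                 oob_scores = c(theta = ft$r.squared,
                                log10_rho_l = fr$r.squared),
                 oob_predictions = data.frame(
                   theta = ft$predictions,
                   log10_rho_l = fr$predictions),
                 train_targets = train$targets,
                 sample_size = train$sample_size,
                 n_trees = as.integer(n_trees),
                 feature_names = colnames(train$features)),
            class = "symbiocoal_rf")
}

# Infinitesimal-jackknife variance of a bagged prediction (Wager, Hastie &
# Efron 2014), with the finite-B Monte Carlo bias correction, from
# per-tree predictions at one point and the inbag count matrix.
ij_variance <- function(tree_pred, inbag) {
  B <- length(tree_pred)
  n <- nrow(inbag)
  tbar <- mean(tree_pred)
  ct <- tree_pred - tbar
  cov_i <- as.numeric(inbag %*% ct) / B  # mean_b((N_ib - Nbar_i)(t_b - tbar))
  v_raw <- sum(cov_i^2)
  v_boot <- sum(ct^2) / B
  max(v_raw - n * v_boot / B, 1e-12)
}

# residual variance of out-of-bag predictions among the k training points
# closest to the new prediction (captures how target spread given the
# summaries varies across the prior)
local_residual_variance <- function(oob_pred, y, p, k = 100L) {
  k <- min(k, length(y))
  r <- y - oob_pred
  idx <- order(abs(oob_pred - p))[seq_len(k)]
  mean(r[idx]^2)
}

rf_predict_ci <- function(forest, feats, oob_pred, y, level = 0.95) {
  pr <- predict(forest, data = as.data.frame(t(feats)), predict.all = TRUE)
  tp <- as.numeric(pr$predictions)
  inbag <- do.call(cbind, forest$inbag.counts)
  v_ij <- ij_variance(tp, inbag)
  point <- mean(tp)
  # predictive variance: forest sampling variance (infinitesimal jackknife)
  # plus local out-of-bag residual variance
  v <- v_ij + local_residual_variance(oob_pred, y, point)
  z <- qnorm(1 - (1 - level) / 2)
  c(estimate = point, lower = point - z * sqrt(v),
    upper = point + z * sqrt(v), se = sqrt(v), se_ij = sqrt(v_ij))
}

#' Estimate theta and rho*l for an observed summary vector
#'
#' Forest point predictions with 95% normal confidence intervals whose
#' variance combines the infinitesimal-jackknife estimate of the forest's
#' own sampling variance with a locally estimated out-of-bag residual
#' variance (the spread of true parameter values around forest predictions
#' among the 100 training simulations with the most similar predictions).
#' The jackknife component alone quantifies only Monte Carlo noise of the
#' forest and would badly understate uncertainty about the parameter; the
#' residual component restores predictive calibration.  The observed
#' vector must have been computed at the sample size the model was
#' trained for.
#'
#' @param model a [fit_rf()] result.
#' @param observed a [summary_vector()].
#' @return list of class `fit_result`: `theta_hat`, `log10_rho_l_hat`,
#'   `rho_l_hat`, `ci` (data frame), `oob_scores`, `sample_size`,
#'   `low_information` flag.
#' @export
estimate <- function(model, observed) {
  stopifnot(inherits(model, "symbiocoal_rf"),
            inherits(observed, "summary_vector"))
  if (observed$n_samples != model$sample_size)
    stop("contract error: observed sample size (", observed$n_samples,
         ") does not match the model's training sample size (",
         model$sample_size, "); train a model per sample size")
  feats <- sv_features(observed)
  low_info <- observed$pi == 0 && observed$watterson == 0
  if (low_info)
    warning("no segregating sites in the observed data: estimates carry ",
            "little information beyond the prior")
  ci_t <- rf_predict_ci(model$forest_theta, feats,
                        model$oob_predictions$theta,
                        model$train_targets$theta)
  ci_r <- rf_predict_ci(model$forest_rho_l, feats,
                        model$oob_predictions$log10_rho_l,
                        model$train_targets$log10_rho_l)
  ci <- data.frame(parameter = c("theta", "log10_rho_l"),
                   estimate = c(ci_t["estimate"], ci_r["estimate"]),
                   lower = c(ci_t["lower"], ci_r["lower"]),
                   upper = c(ci_t["upper"], ci_r["upper"]),
                   se = c(ci_t["se"], ci_r["se"]), row.names = NULL)
  structure(list(theta_hat = unname(ci_t["estimate"]),
                 log10_rho_l_hat = unname(ci_r["estimate"]),
                 rho_l_hat = 10^unname(ci_r["estimate"]),
                 ci = ci, oob_scores = model$oob_scores,
                 sample_size = model$sample_size,
                 low_information = low_info),
            class = "fit_result")
}

#' Convert a recombination-rate estimate to r/m
#'
#' `r/m = rho*l * theta_recombinant / theta_genome`: the ratio of
#' nucleotide changes introduced by recombination to those introduced by
#' mutation.  When donor and genome diversity coincide, r/m equals rho*l.
#'
#' @param rho_l per-site rho*l estimate.
#' @param theta_recombinant diversity of recombining fragments.
#' @param theta_genome genome-wide diversity (> 0).
#' @return list of class `rate_summary`: `rho_l`, `theta_recombinant`,
#'   `theta_genome`, `r_over_m`.
#' @export
r_over_m <- function(rho_l, theta_recombinant, theta_genome) {
  if (theta_genome <= 0) stop("theta_genome must be > 0")
  structure(list(rho_l = rho_l, theta_recombinant = theta_recombinant,
                 theta_genome = theta_genome,
                 r_over_m = rho_l * theta_recombinant / theta_genome),
            class = "rate_summary")
}
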