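#' Simulation configuration for two-condition junction-count data
#'
#' Defines the generative model behind [simulate_dataset()]: per event and
#' sample a total junction depth is drawn from a negative binomial
#' (mean `depth_mean`, size `depth_dispersion`; large size approaches
#' Poisson), truncated at >= 1, and the inclusion count is binomial at the
#' condition's true PSI. Control-condition true PSIs are uniform on
#' `psi_base_range`; a fraction `effect_fraction` of events receives a true
#' delta-PSI drawn from `effect_sizes` (sign set positive with probability
#' `direction_bias`, per event type if a named vector), clipped so PSIs stay
#' in \[0.01, 0.99\].
#'
#' @param n_events_per_type Named integer vector, events per type
#'   (default 250 of each of ES, IR, Alt5, Alt3).
#' @param n_reps Named integer vector, replicates per condition
#'   (default `c(control = 3, knockdown = 3)`).
#' @param depth_mean Mean total junction reads per event per sample
#'   (default 50).
#' @param depth_dispersion Negative-binomial size parameter (default 10).
#' @param psi_base_range Range of control-condition true PSIs
#'   (default `c(0.05, 0.95)`).
#' @param effect_fraction Fraction of events with a true delta-PSI
#'   (default 0.2).
#' @param effect_sizes Magnitudes of true |delta-PSI| sampled with
#'   `effect_weights` (default 0.10, 0.20, 0.30, equal weights).
#' @param effect_weights Selection weights for `effect_sizes`.
#' @param direction_bias Probability that an effect is positive; scalar, or a
#'   named vector per event type (default 0.5).
#' @param seed Integer seed; the dataset is a deterministic function of the
#'   config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_events_per_type = c(ES = 250, IR = 250,
                                             Alt5 = 250, Alt3 = 250),
                       n_reps = c(control = 3, knockdown = 3),
                       depth_mean = 50, depth_dispersion = 10,
                       psi_base_range = c(0.05, 0.95),
                       effect_fraction = 0.2,
                       effect_sizes = c(0.10, 0.20, 0.30),
                       effect_weights = NULL,
                       direction_bias = 0.5,
                       seed = 1L) {
  if (is.null(names(n_events_per_type)) ||
      !all(names(n_events_per_type) %in% event_types())) {
    abort("`n_events_per_type` must be named with event types")
  }
  if (any(n_events_per_type < 0) || !all(is_whole(n_events_per_type))) {
    abort("event counts must be non-negative integers")
  }
  if (length(n_reps) != 2 || is.null(names(n_reps)) ||
      any(n_reps < 1) || !all(is_whole(n_reps))) {
    abort("`n_reps` must be a named length-2 vector of positive integers")
  }
  if (depth_mean <= 0 || depth_dispersion <= 0) {
    abort("depth parameters must be positive")
  }
  if (effect_fraction < 0 || effect_fraction > 1) {
    abort("`effect_fraction` must be in [0, 1]")
  }
  if (any(effect_sizes <= 0) || any(effect_sizes >= 1)) {
    abort("`effect_sizes` must be in (0, 1)")
  }
  if (is.null(effect_weights)) {
    effect_weights <- rep(1, length(effect_sizes))
  }
  if (any(direction_bias < 0) || any(direction_bias > 1)) {
    abort("`direction_bias` must be in [0, 1]")
  }
  if (!is_whole(seed)) abort("`seed` must be an integer")
  structure(list(
    n_events_per_type = n_events_per_type, n_reps = n_reps,
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    psi_base_range = psi_base_range, effect_fraction = effect_fraction,
    effect_sizes = effect_sizes, effect_weights = effect_weights,
    direction_bias = direction_bias, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Coverage score from total junction depth
#'
#' The dialect used by the simulator and table writer: `N` below 10 reads,
#' `VLOW` in \[10, 20), `LOW` in \[20, 40), `OK` in \[40, 100), `SOK` at 100
#' and above.
#'
#' @param total_depth Non-negative integer vector of total junction reads
#'   (`inc + exc`).
#' @return Ordered factor of coverage scores.
#' @export
#' @examples
#' assign_coverage_score(c(0, 10, 25, 50, 100))
assign_coverage_score <- function(total_depth) {
  if (any(total_depth < 0) || !all(is_whole(total_depth))) {
    abort("`total_depth` must be non-negative integers")
  }
  lv <- coverage_levels()
  idx <- findInterval(total_depth, c(10, 20, 40, 100)) + 1L
  factor(lv[idx], levels = lv, ordered = TRUE)
}

# NB depth truncated at >= 1: redraw zeros so the shape above 0 is preserved
rnbinom_pos <- function(n, mu, size) {
  d <- rnbinom(n, mu = mu, size = size)
  while (any(d == 0)) {
    i <- which(d == 0)
    d[i] <- rnbinom(length(i), mu = mu, size = size)
  }
  d
}

#' Simulate a two-condition splicing dataset with known truth
#'
#' Generates splicing events, per-sample junction counts, coverage scores,
#' the study design and a ground-truth table, all deterministically from the
#' config's seed. See [sim_config()] for the generative model.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `events` (a `splice_events` tibble),
#'   `truth` (tibble: `event_id`, `event_type`, `true_psi_control`,
#'   `true_psi_knockdown`, `true_delta`, `is_effect`) and `design`
#'   (a `study_design`; reference is the first condition named in `n_reps`).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(
#'   n_events_per_type = c(ES = 10, IR = 10, Alt5 = 0, Alt3 = 0), seed = 42))
#' dplyr::count(sim$events, sample_id)
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  set.seed(config$seed)
  conds <- names(config$n_reps)
  reference <- conds[1]
  sample_ids <- unlist(lapply(conds, function(cd) {
    paste0(cd, "_", seq_len(config$n_reps[[cd]]))
  }))
  design <- study_design(
    tibble::tibble(sample_id = sample_ids,
                   condition = rep(conds, config$n_reps)),
    reference = reference
  )

  types <- rep(names(config$n_events_per_type), config$n_events_per_type)
  n_ev <- length(types)
  if (n_ev == 0) abort("config generates zero events")
  event_ids <- sprintf("EV%05d", seq_len(n_ev))

  psi_ctrl <- runif(n_ev, config$psi_base_range[1], config$psi_base_range[2])
  is_effect <- runif(n_ev) < config$effect_fraction
  mag <- sample(config$effect_sizes, n_ev, replace = TRUE,
                prob = config$effect_weights)
  bias <- config$direction_bias
  p_pos <- if (length(bias) == 1) rep(bias, n_ev) else {
    if (is.null(names(bias)) || !all(types %in% names(bias))) {
      abort("named `direction_bias` must cover all simulated event types")
    }
    unname(bias[types])
  }
  sgn <- ifelse(runif(n_ev) < p_pos, 1, -1)
  delta <- ifelse(is_effect, sgn * mag, 0)
  psi_kd <- pmin(0.99, pmax(0.01, psi_ctrl + delta))
  psi_ctrl <- pmin(0.99, pmax(0.01, psi_ctrl))
  delta <- psi_kd - psi_ctrl
  is_effect <- delta != 0

  truth <- tibble::tibble(
    event_id = event_ids,
    event_type = factor(types, levels = event_types()),
    true_psi_control = psi_ctrl,
    true_psi_knockdown = psi_kd,
    true_delta = delta,
    is_effect = is_effect
  )

  n_s <- length(sample_ids)
  long <- tidyr::expand_grid(event_id = event_ids, sample_id = sample_ids)
  long <- dplyr::left_join(long, truth[c("event_id", "event_type",
                                         "true_psi_control",
                                         "true_psi_knockdown")],
                           by = "event_id")
  long <- dplyr::left_join(long, design, by = "sample_id")
  true_psi <- ifelse(long$condition == reference,
                     long$true_psi_control, long$true_psi_knockdown)
  depth <- rnbinom_pos(n_ev * n_s, mu = config$depth_mean,
                       size = config$depth_dispersion)
  inc <- rbinom(n_ev * n_s, size = depth, prob = true_psi)
  events <- splice_events(tibble::tibble(
    event_id = long$event_id,
    gene_id = paste0("gene_", long$event_id),
    event_type = long$event_type,
    sample_id = long$sample_id,
    inc = inc,
    exc = depth - inc,
    coverage = as.character(assign_coverage_score(depth))
  ))
  list(events = events, truth = truth, design = design)
}

#' Compare differential calls against simulation truth
#'
#' @param results Per-event results tibble (or a `diffsplice_fit`).
#' @param truth Truth tibble from [simulate_dataset()].
#' @return One-row tibble: `sensitivity` (called effect events over all
#'   effect events), `false_discovery_proportion` (called null events over
#'   all called events; 0 when nothing is called) and `sign_accuracy` (among
#'   called effect events, fraction whose delta-PSI sign matches the truth;
#'   `NA` when none).
#' @export
evaluate_calls <- function(results, truth) {
  if (inherits(results, "diffsplice_fit")) results <- results$results
  unknown <- setdiff(results$event_id, truth$event_id)
  if (length(unknown) > 0) {
    abort(sprintf("result event '%s' has no truth record", unknown[1]))
  }
  joined <- dplyr::inner_join(
    results[c("event_id", "delta_psi", "significant")],
    truth[c("event_id", "true_delta", "is_effect")],
    by = "event_id"
  )
  called <- joined[joined$significant, , drop = FALSE]
  n_effect <- sum(joined$is_effect)
  sens <- if (n_effect == 0) NA_real_ else {
    sum(called$is_effect) / n_effect
  }
  fdp <- if (nrow(called) == 0) 0 else sum(!called$is_effect) / nrow(called)
  eff_called <- called[called$is_effect, , drop = FALSE]
  sgn_acc <- if (nrow(eff_called) == 0) NA_real_ else {
    mean(sign(eff_called$delta_psi) == sign(eff_called$true_delta))
  }
  tibble::tibble(sensitivity = sens, false_discovery_proportion = fdp,
                 sign_accuracy = sgn_acc)
}
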