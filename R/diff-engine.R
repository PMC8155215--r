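#' Differential-calling thresholds
#'
#' Bundles the tunable parameters of the resampling engine: the number of
#' beta emissions per sample (`n_emit`, default 500), the direction-probability
#' threshold (`prob_threshold`, default 0.8) and the minimum absolute
#' delta-PSI (`dpsi_threshold`, default 0.05, i.e. 5 percentage points). An
#' event is called significant only when both inequalities hold strictly.
#'
#' @param prob_threshold Probability threshold in \[0.5, 1).
#' @param dpsi_threshold Minimum |delta-PSI| as a fraction in (0, 1).
#' @param n_emit Number of beta emissions per sample (>= 1).
#' @return A list of class `call_thresholds`.
#' @export
call_thresholds <- function(prob_threshold = 0.8, dpsi_threshold = 0.05,
                            n_emit = 500L) {
  if (!is.numeric(prob_threshold) || length(prob_threshold) != 1 ||
      prob_threshold < 0.5 || prob_threshold >= 1) {
    abort("`prob_threshold` must be a single number in [0.5, 1)")
  }
  if (!is.numeric(dpsi_threshold) || length(dpsi_threshold) != 1 ||
      dpsi_threshold <= 0 || dpsi_threshold >= 1) {
    abort("`dpsi_threshold` must be a single number in (0, 1)")
  }
  if (!is_whole(n_emit) || n_emit < 1) {
    abort("`n_emit` must be a positive integer")
  }
  structure(list(prob_threshold = prob_threshold,
                 dpsi_threshold = dpsi_threshold,
                 n_emit = as.integer(n_emit)),
            class = "call_thresholds")
}

#' Emit beta-distributed PSI pseudo-samples for one sample
#'
#' Draws `n_emit` values from `Beta(inc + 1, exc + 1)`. The spread of the
#' draws encodes the read-coverage uncertainty of the sample's PSI: deep
#' events give narrow emissions, shallow events wide ones. Draws consume the
#' current RNG stream, so results are reproducible under `set.seed()`.
#'
#' @inheritParams beta_params
#' @param n_emit Number of draws (default 500).
#' @return Numeric vector of `n_emit` values, each strictly in (0, 1).
#' @export
#' @examples
#' set.seed(1)
#' mean(emit_psi(10, 30, n_emit = 5000)) # near 11/42
emit_psi <- function(inc, exc, n_emit = 500L) {
  check_counts(inc, exc)
  if (length(inc) != 1) abort("`emit_psi` emits for a single sample")
  if (!is_whole(n_emit) || n_emit < 1) {
    abort("`n_emit` must be a positive integer")
  }
  rbeta(n_emit, inc + 1, exc + 1)
}

#' Pool emitted PSI values per condition
#'
#' Emits `n_emit` beta values for every sample of one event and concatenates
#' them per condition, so each condition's pooled vector has length
#' `n_emit * n_replicates`.
#'
#' @param event One event's rows of a `splice_events` table (single
#'   `event_id`).
#' @param design A `study_design`.
#' @param n_emit Emissions per sample.
#' @return Named list of two numeric vectors, one per condition.
#' @export
pooled_condition_values <- function(event, design, n_emit = 500L) {
  if (length(unique(event$event_id)) != 1) {
    abort("`event` must contain exactly one event_id")
  }
  missing_s <- setdiff(event$sample_id, design$sample_id)
  if (length(missing_s) > 0) {
    abort(sprintf("sample '%s' of event '%s' is not in the design",
                  missing_s[1], event$event_id[1]))
  }
  # iterate in design order so the draw sequence is independent of row order
  idx <- match(design$sample_id, event$sample_id)
  keep <- !is.na(idx)
  pooled <- split(idx[keep], design$condition[keep])
  lapply(pooled, function(rows) {
    unlist(lapply(rows, function(i) {
      emit_psi(event$inc[i], event$exc[i], n_emit)
    }), use.names = FALSE)
  })
}

#' Condition-level PSI from pooled emissions
#'
#' The global PSI of a condition is the median of all emitted values pooled
#' across that condition's replicates.
#'
#' @param pooled Non-empty numeric vector of pooled emission values.
#' @return The median, a fraction in (0, 1).
#' @export
condition_psi <- function(pooled) {
  if (length(pooled) == 0) abort("pooled emission vector is empty")
  median(pooled)
}

#' Probability that the test condition's PSI exceeds the reference's
#'
#' Shuffles the two pooled emission vectors independently, truncates the
#' longer to the shorter length (a random subsample, relevant only for
#' unbalanced designs), forms elementwise differences `kd - ctrl`, and
#' returns the fraction of differences strictly greater than zero. With
#' independent emissions this estimates P(PSI_test > PSI_ref) under the
#' per-sample beta uncertainty model.
#'
#' @param pooled_kd,pooled_ctrl Non-empty numeric vectors of pooled emissions
#'   for the test and reference condition.
#' @return A fraction in \[0, 1\].
#' @export
prob_positive <- function(pooled_kd, pooled_ctrl) {
  if (length(pooled_kd) == 0 || length(pooled_ctrl) == 0) {
    abort("pooled emission vectors must be non-empty")
  }
  kd <- sample(pooled_kd)
  ctrl <- sample(pooled_ctrl)
  n <- min(length(kd), length(ctrl))
  mean(kd[seq_len(n)] - ctrl[seq_len(n)] > 0)
}

# per-event computation; assumes the caller has set the RNG state
differential_event_impl <- function(event, design, thresholds) {
  pooled <- pooled_condition_values(event, design, thresholds$n_emit)
  ref <- attr(design, "reference")
  tst <- attr(design, "test")
  if (is.null(pooled[[ref]]) || is.null(pooled[[tst]])) {
    abort(sprintf("event '%s' lacks samples in one condition",
                  event$event_id[1]))
  }
  psi_ctrl <- condition_psi(pooled[[ref]])
  psi_kd <- condition_psi(pooled[[tst]])
  p_pos <- prob_positive(pooled[[tst]], pooled[[ref]])
  p_diff <- max(p_pos, 1 - p_pos)
  delta <- psi_kd - psi_ctrl
  tibble::tibble(
    event_id = event$event_id[1],
    event_type = event$event_type[1],
    psi_control = psi_ctrl,
    psi_knockdown = psi_kd,
    delta_psi = delta,
    prob_positive = p_pos,
    prob_differential = p_diff,
    significant = p_diff > thresholds$prob_threshold &
      abs(delta) > thresholds$dpsi_threshold
  )
}

#' Differential splicing result for a single event
#'
#' Runs the full resampling computation for one event: per-sample beta
#' emissions, per-condition pooling and medians, delta-PSI
#' (test minus reference), the probability of a positive difference, its
#' direction-symmetric version `prob_differential = max(p, 1 - p)`, and the
#' significance call (`prob_differential > prob_threshold` and
#' `|delta_psi| > dpsi_threshold`, both strict).
#'
#' @param event One event's rows of a `splice_events` table.
#' @param design A `study_design`.
#' @param thresholds A [call_thresholds()] object.
#' @param seed Optional integer seed applied before emission.
#' @return One-row tibble (see [run_differential()] for columns).
#' @export
differential_event <- function(event, design, thresholds = call_thresholds(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  differential_event_impl(event, design, thresholds)
}

#' Run the differential splicing analysis over all events
#'
#' Applies the coverage filter, then computes one differential result per
#' surviving event. Each event uses its own RNG substream derived from
#' `seed` and a stable hash of its `event_id`, so results are identical
#' regardless of event order and unaffected by adding or removing other
#' events.
#'
#' @param events A `splice_events` tibble (long, one row per event/sample).
#' @param design A `study_design`.
#' @param thresholds A [call_thresholds()] object.
#' @param seed Master integer seed (required for reproducibility).
#' @param min_coverage Coverage threshold applied to all samples
#'   (default `"VLOW"`).
#' @return An object of class `diffsplice_fit`: a list with `results` (tibble
#'   with columns `event_id`, `event_type`, `psi_control`, `psi_knockdown`,
#'   `delta_psi`, `prob_positive`, `prob_differential`, `significant`),
#'   `n_input`, `n_dropped_coverage`, `thresholds`, `min_coverage`, `seed`
#'   and the design. Use [tidy()] / [glance()] to extract tibbles.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(
#'   n_events_per_type = c(ES = 5, IR = 5, Alt5 = 0, Alt3 = 0), seed = 7))
#' fit <- run_differential(sim$events, sim$design, seed = 7)
#' tidy(fit)
run_differential <- function(events, design, thresholds = call_thresholds(),
                             seed, min_coverage = "VLOW") {
  if (missing(seed) || !is_whole(seed)) {
    abort("`seed` must be supplied as a single integer")
  }
  if (!inherits(events, "splice_events")) events <- splice_events(events)
  missing_s <- setdiff(unique(events$sample_id), design$sample_id)
  if (length(missing_s) > 0) {
    abort(sprintf("sample '%s' is not in the design", missing_s[1]))
  }
  n_input <- length(unique(events$event_id))
  keep_ids <- if (n_input == 0) character() else {
    pass <- coverage_pass(events, min_coverage)
    pass$event_id[pass$pass]
  }
  kept <- events[events$event_id %in% keep_ids, , drop = FALSE]
  n_dropped <- n_input - length(keep_ids)

  results <- if (length(keep_ids) == 0) {
    tibble::tibble(
      event_id = character(), event_type = factor(character(),
                                                  levels = event_types()),
      psi_control = numeric(), psi_knockdown = numeric(),
      delta_psi = numeric(), prob_positive = numeric(),
      prob_differential = numeric(), significant = logical()
    )
  } else {
    chunks <- split(as.data.frame(kept), kept$event_id)
    purrr::list_rbind(purrr::map(chunks, function(ev) {
      set.seed(event_seed(seed, ev$event_id[1]))
      differential_event_impl(ev, design, thresholds)
    }))
  }
  results <- dplyr::arrange(results, .data$event_id)
  structure(
    list(results = results, n_input = n_input,
         n_dropped_coverage = n_dropped, thresholds = thresholds,
         min_coverage = min_coverage, seed = as.integer(seed),
         design = design),
    class = "diffsplice_fit"
  )
}

#' @export
print.diffsplice_fit <- function(x, ...) {
  cat("Differential splicing fit\n")
  cat(sprintf("  events: %d input, %d dropped by coverage (< %s), %d tested\n",
              x$n_input, x$n_dropped_coverage, x$min_coverage,
              nrow(x$results)))
  cat(sprintf("  called significant: %d (prob > %.2f, |dPSI| > %.1f%%)\n",
              sum(x$results$significant), x$thresholds$prob_threshold,
              100 * x$thresholds$dpsi_threshold))
  cat(sprintf("  n_emit = %d, seed = %d, reference = %s\n",
              x$thresholds$n_emit, x$seed, attr(x$design, "reference")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-event results of a differential splicing fit
#'
#' @param x A `diffsplice_fit`.
#' @param ... Unused.
#' @return The per-event results tibble.
#' @export
tidy.diffsplice_fit <- function(x, ...) x$results

#' One-row summary of a differential splicing fit
#'
#' @param x A `diffsplice_fit`.
#' @param ... Unused.
#' @return One-row tibble: event counts at each pipeline stage plus the
#'   effective parameters.
#' @export
glance.diffsplice_fit <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_dropped_coverage = x$n_dropped_coverage,
    n_tested = nrow(x$results),
    n_significant = sum(x$results$significant),
    prob_threshold = x$thresholds$prob_threshold,
    dpsi_threshold = x$thresholds$dpsi_threshold,
    n_emit = x$thresholds$n_emit,
    min_coverage = x$min_coverage,
    seed = x$seed
  )
}
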