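#' Ordered coverage-score vocabulary
#'
#' Per-sample read-coverage quality labels for a splicing event, ordered from
#' worst to best: `N < VLOW < LOW < OK < SOK`. Events are typically kept only
#' when every sample scores at least `VLOW`.
#'
#' @return Character vector of the five levels, worst first.
#' @export
#' @examples
#' coverage_levels()
coverage_levels <- function() c("N", "VLOW", "LOW", "OK", "SOK")

#' Construct a coverage score factor
#'
#' Validates score strings against the fixed five-level vocabulary and returns
#' an ordered factor. Unknown strings are rejected rather than coerced, so
#' dialect drift in input tables fails loudly.
#'
#' @param x Character vector of score labels.
#' @return Ordered factor with levels `N < VLOW < LOW < OK < SOK`.
#' @export
#' @examples
#' coverage_score(c("VLOW", "SOK"))
coverage_score <- function(x) {
  x <- as.character(x)
  bad <- !(x %in% coverage_levels())
  if (any(bad)) {
    abort(sprintf(
      "unknown coverage score '%s' (allowed: %s)",
      x[which(bad)[1]], paste(coverage_levels(), collapse = " < ")
    ))
  }
  factor(x, levels = coverage_levels(), ordered = TRUE)
}

#' Event-type vocabulary
#'
#' The four alternative-splicing event classes: exon skipping (`ES`), intron
#' retention (`IR`), and alternative 5' / 3' splice-site choice
#' (`Alt5` / `Alt3`).
#'
#' @return Character vector of the four event types.
#' @export
event_types <- function() c("ES", "IR", "Alt5", "Alt3")

#' Beta emission parameters from junction counts
#'
#' The inclusion/exclusion junction counts of one sample parameterise a beta
#' distribution with `alpha = inc + 1` and `beta = exc + 1` (the conjugate
#' posterior of a binomial inclusion model under a uniform prior). The +1
#' terms keep both shape parameters strictly positive even at zero coverage.
#'
#' @param inc,exc Non-negative integer vectors of junction reads supporting
#'   inclusion and exclusion.
#' @return A tibble with columns `alpha` and `beta`.
#' @export
#' @examples
#' beta_params(inc = 10, exc = 30)
beta_params <- function(inc, exc) {
  check_counts(inc, exc)
  tibble::tibble(alpha = as.integer(round(inc)) + 1L,
                 beta  = as.integer(round(exc)) + 1L)
}

#' Mean of the beta emission distribution
#'
#' `(inc + 1) / (inc + exc + 2)`: a shrunken approximation of the empirical
#' PSI that is always strictly inside (0, 1).
#'
#' @inheritParams beta_params
#' @return Numeric vector of beta means, each in (0, 1).
#' @export
#' @examples
#' beta_mean(10, 30) # 11/42
beta_mean <- function(inc, exc) {
  check_counts(inc, exc)
  (inc + 1) / (inc + exc + 2)
}

#' Empirical percent-spliced-in from junction counts
#'
#' `inc / (inc + exc)` as a fraction in \[0, 1\]; `NA` when a sample has no
#' junction reads at all (0 and 0.5 are meaningful PSIs, so zero coverage is
#' an explicit missing value, never a number).
#'
#' @inheritParams beta_params
#' @return Numeric vector; `NA` where `inc + exc == 0`.
#' @export
#' @examples
#' empirical_psi(c(30, 0), c(10, 0))
empirical_psi <- function(inc, exc) {
  check_counts(inc, exc)
  out <- ifelse(inc + exc > 0, inc / (inc + exc), NA_real_)
  as.numeric(out)
}

#' Assemble and validate a splicing-event table
#'
#' The package's tabular representation of splicing events is long: one row
#' per event per sample, with columns `event_id`, `gene_id`, `event_type`,
#' `sample_id`, `inc`, `exc`, `coverage` and `psi`. This constructor checks
#' the invariants (valid counts, known event types and coverage scores, one
#' row per event/sample pair, `psi` missing exactly when `inc + exc == 0`)
#' and recomputes `psi` when absent.
#'
#' @param x Data frame with at least `event_id`, `gene_id`, `event_type`,
#'   `sample_id`, `inc`, `exc`, `coverage`. A `psi` column is recomputed if
#'   missing.
#' @return A validated tibble of class `splice_events`.
#' @export
splice_events <- function(x) {
  need <- c("event_id", "gene_id", "event_type", "sample_id", "inc", "exc",
            "coverage")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  check_counts(x$inc, x$exc)
  bad_type <- !(as.character(x$event_type) %in% event_types())
  if (any(bad_type)) {
    abort(sprintf("unknown event_type '%s' (allowed: %s)",
                  as.character(x$event_type)[which(bad_type)[1]],
                  paste(event_types(), collapse = ", ")))
  }
  dup <- duplicated(x[c("event_id", "sample_id")])
  if (any(dup)) {
    abort(sprintf("duplicate event/sample pair: %s / %s",
                  x$event_id[which(dup)[1]], x$sample_id[which(dup)[1]]))
  }
  x$inc <- as.integer(round(x$inc))
  x$exc <- as.integer(round(x$exc))
  x$event_type <- factor(as.character(x$event_type), levels = event_types())
  x$coverage <- coverage_score(x$coverage)
  x$psi <- empirical_psi(x$inc, x$exc)
  class(x) <- c("splice_events", class(x))
  x
}

#' Define a two-condition study design
#'
#' Maps sample ids to exactly two condition labels and designates one as the
#' reference ("control"); the other is the test ("knockdown") condition whose
#' PSI shift defines the sign of delta-PSI.
#'
#' @param x Data frame with columns `sample_id` and `condition`.
#' @param reference The condition label to use as reference. Defaults to the
#'   first label in sorted order.
#' @return A tibble of class `study_design` with attributes `reference` and
#'   `test`.
#' @export
#' @examples
#' study_design(
#'   data.frame(sample_id = c("c1", "c2", "k1", "k2"),
#'              condition = c("ctrl", "ctrl", "kd", "kd")),
#'   reference = "ctrl"
#' )
study_design <- function(x, reference = NULL) {
  if (!all(c("sample_id", "condition") %in% names(x))) {
    abort("design needs columns `sample_id` and `condition`")
  }
  x <- tibble::as_tibble(x[c("sample_id", "condition")])
  x$sample_id <- as.character(x$sample_id)
  x$condition <- as.character(x$condition)
  if (nrow(x) == 0) abort("design is empty")
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("duplicate sample_id '%s' in design",
                  x$sample_id[which(duplicated(x$sample_id))[1]]))
  }
  conds <- sort(unique(x$condition))
  if (length(conds) != 2) {
    abort(sprintf("design must have exactly 2 conditions, found %d (%s)",
                  length(conds), paste(conds, collapse = ", ")))
  }
  if (is.null(reference)) reference <- conds[1]
  if (!reference %in% conds) {
    abort(sprintf("reference condition '%s' not among design conditions (%s)",
                  reference, paste(conds, collapse = ", ")))
  }
  attr(x, "reference") <- reference
  attr(x, "test") <- setdiff(conds, reference)
  class(x) <- c("study_design", class(x))
  x
}

#' Coverage filter across samples
#'
#' An event passes when every one of its samples has a coverage score at
#' least `min_score` under the order `N < VLOW < LOW < OK < SOK`. The default
#' threshold `VLOW` keeps events quantifiable in all samples.
#'
#' @param events A `splice_events` tibble.
#' @param min_score Minimum coverage score label (default `"VLOW"`).
#' @return A tibble with one row per event: `event_id`, `pass`.
#' @export
coverage_pass <- function(events, min_score = "VLOW") {
  if (nrow(events) == 0) abort("no samples: events table is empty")
  min_score <- coverage_score(min_score)
  events |>
    dplyr::group_by(.data$event_id) |>
    dplyr::summarise(pass = all(.data$coverage >= min_score),
                     .groups = "drop")
}
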