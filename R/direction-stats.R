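#' Direction counts for one event type
#'
#' Among the significant (called) events of a given type, counts how many
#' shifted towards inclusion in the test condition (`delta_psi > 0`,
#' strictly) versus the total number called.
#'
#' @param results Per-event results tibble (from [tidy()] on a
#'   `diffsplice_fit`).
#' @param event_type One of `"ES"`, `"IR"`, `"Alt5"`, `"Alt3"`.
#' @return Named integer vector `c(n_positive, n_total)`; `(0, 0)` when no
#'   significant events of that type exist.
#' @export
direction_counts <- function(results, event_type) {
  if (!event_type %in% event_types()) {
    abort(sprintf("unknown event_type '%s'", event_type))
  }
  sel <- results$significant & as.character(results$event_type) == event_type
  c(n_positive = sum(results$delta_psi[sel] > 0), n_total = sum(sel))
}

#' Continuity-corrected one-sample proportion test
#'
#' Pearson's chi-squared test of a binomial proportion against `null_p` with
#' Yates continuity correction, the correction capped at the observed
#' deviation so that an exact-null observation gives `chi2 = 0`, `p = 1`:
#' \deqn{\chi^2 = (|k - n p_0| - \min(0.5, |k - n p_0|))^2 /
#'       (n p_0 (1 - p_0))}
#' with the p-value from the chi-squared distribution on 1 degree of freedom
#' (two-sided).
#'
#' @param n_positive Number of successes (here: positive delta-PSI calls).
#' @param n_total Number of trials (all calls of the type); must be >= 1.
#' @param null_p Null proportion (default 0.5).
#' @return Named list with `chi2` and `p_value`.
#' @export
#' @examples
#' proportion_test(805, 849)
proportion_test <- function(n_positive, n_total, null_p = 0.5) {
  if (!is_whole(n_total) || n_total < 1) {
    abort("`n_total` must be a positive integer (test undefined at 0)")
  }
  if (!is_whole(n_positive) || n_positive < 0 || n_positive > n_total) {
    abort("`n_positive` must be an integer in [0, n_total]")
  }
  dev <- abs(n_positive - n_total * null_p)
  correction <- min(0.5, dev)
  chi2 <- (dev - correction)^2 / (n_total * null_p * (1 - null_p))
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Wilson score interval with continuity correction
#'
#' The confidence interval dual to [proportion_test()]: the Wilson score
#' interval for a binomial proportion, continuity-corrected with the same
#' capped correction term, clipped to \[0, 1\].
#'
#' @inheritParams proportion_test
#' @param conf_level Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' proportion_ci(805, 849)
proportion_ci <- function(n_positive, n_total, conf_level = 0.95,
                          null_p = 0.5) {
  if (!is_whole(n_total) || n_total < 1) {
    abort("`n_total` must be a positive integer (interval undefined at 0)")
  }
  if (!is_whole(n_positive) || n_positive < 0 || n_positive > n_total) {
    abort("`n_positive` must be an integer in [0, n_total]")
  }
  n <- n_total
  est <- n_positive / n
  z <- qnorm((1 + conf_level) / 2)
  z2 <- z^2
  cc <- min(0.5, abs(n_positive - n * null_p))
  p_u <- est + cc / n
  p_l <- est - cc / n
  hi <- if (p_u >= 1) 1 else {
    (p_u + z2 / (2 * n) + z * sqrt(p_u * (1 - p_u) / n + z2 / (4 * n^2))) /
      (1 + z2 / n)
  }
  lo <- if (p_l <= 0) 0 else {
    (p_l + z2 / (2 * n) - z * sqrt(p_l * (1 - p_l) / n + z2 / (4 * n^2))) /
      (1 + z2 / n)
  }
  c(ci_low = max(0, lo), ci_high = min(1, hi))
}

#' Direction-of-change summary per event type
#'
#' For each event type present in the results, counts significant events
#' with positive delta-PSI, and tests the null that the proportion of
#' positive shifts equals 0.5 with the continuity-corrected chi-squared
#' proportion test and its Wilson confidence interval. Types present in the
#' results but without significant events are reported with `NA` test fields
#' rather than dropped.
#'
#' @param results Per-event results tibble, or a `diffsplice_fit`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param null_p Null proportion (default 0.5).
#' @return A tibble of class `direction_summary`, one row per event type:
#'   `event_type`, `n_positive`, `n_total`, `proportion`, `proportion_pct`
#'   (rounded half-up to 2 decimals), `chi2`, `p_value`, `ci_low`, `ci_high`,
#'   `conf_level`.
#' @export
#' @examples
#' res <- tibble::tibble(
#'   event_id = paste0("e", 1:3), event_type = c("IR", "IR", "IR"),
#'   delta_psi = c(0.1, 0.2, -0.1), significant = TRUE
#' )
#' summarize_directions(res)
summarize_directions <- function(results, conf_level = 0.95, null_p = 0.5) {
  if (inherits(results, "diffsplice_fit")) results <- results$results
  types <- intersect(event_types(), unique(as.character(results$event_type)))
  rows <- purrr::map(types, function(tp) {
    cnt <- direction_counts(results, tp)
    k <- unname(cnt["n_positive"])
    n <- unname(cnt["n_total"])
    if (n == 0) {
      tibble::tibble(event_type = tp, n_positive = 0L, n_total = 0L,
                     proportion = NA_real_, proportion_pct = NA_real_,
                     chi2 = NA_real_, p_value = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, conf_level = conf_level)
    } else {
      tst <- proportion_test(k, n, null_p)
      ci <- proportion_ci(k, n, conf_level, null_p)
      tibble::tibble(event_type = tp, n_positive = as.integer(k),
                     n_total = as.integer(n), proportion = k / n,
                     proportion_pct = round_half_up(100 * k / n, 2),
                     chi2 = tst$chi2, p_value = tst$p_value,
                     ci_low = unname(ci["ci_low"]),
                     ci_high = unname(ci["ci_high"]),
                     conf_level = conf_level)
    }
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("direction_summary", class(out))
  out
}
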