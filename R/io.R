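#' @importFrom readr read_tsv write_tsv cols col_character
NULL

fmt_pct <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"),
                                 round_half_up(100 * x, digits)))
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

# "SCORE@inc,exc" -> list(score, inc, exc); lenient mode additionally accepts
# extra comma-separated fields after exc and "inc,exc@SCORE" orderings seen
# in other tools' dialects. Fractional counts are rounded half-to-even with
# a warning (mapability correction can yield non-integers upstream).
parse_q_string <- function(q, lenient = FALSE) {
  parts <- strsplit(q, "@", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(NULL)
  score <- parts[1]
  counts <- strsplit(parts[2], ",", fixed = TRUE)[[1]]
  if (lenient && !(score %in% coverage_levels())) {
    # variant: "inc,exc@SCORE"
    alt_counts <- strsplit(parts[1], ",", fixed = TRUE)[[1]]
    if (parts[2] %in% coverage_levels() && length(alt_counts) >= 2) {
      score <- parts[2]
      counts <- alt_counts
    }
  }
  if (!(score %in% coverage_levels())) return(NULL)
  if (length(counts) < 2 || (!lenient && length(counts) != 2)) return(NULL)
  inc <- suppressWarnings(as.numeric(counts[1]))
  exc <- suppressWarnings(as.numeric(counts[2]))
  if (is.na(inc) || is.na(exc) || inc < 0 || exc < 0) return(NULL)
  if (!is_whole(inc) || !is_whole(exc)) {
    warn(sprintf("fractional junction counts in '%s' rounded half-to-even", q))
  }
  # raw values are kept so PSI consistency is judged against the counts as
  # printed, before the integer rounding used for the beta parametrization
  list(score = score, inc = as.integer(round(inc)),
       exc = as.integer(round(exc)), raw_inc = inc, raw_exc = exc)
}

#' Read a splicing-event inclusion table
#'
#' Expects a TSV with leading columns `EVENT`, `GENE`, `TYPE` followed by one
#' pair of columns per sample: `<sample>.PSI` (percentage with 2 decimals, or
#' `NA` for zero-coverage samples) and `<sample>.Q` (quality string
#' `SCORE@inc,exc` with `SCORE` one of `N`, `VLOW`, `LOW`, `OK`, `SOK`).
#' PSI/count consistency is checked to 0.5 percentage points; violations and
#' unparseable fields are reported with row and column.
#'
#' @param path Path to the TSV file.
#' @param lenient Accept common external variants of the quality string
#'   (extra trailing fields, `inc,exc@SCORE` ordering); what cannot be
#'   mapped is still rejected.
#' @return A `splice_events` tibble (long form).
#' @export
read_inclusion_table <- function(path, lenient = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  hdr <- names(raw)
  if (length(hdr) < 5 || !identical(hdr[1:3], c("EVENT", "GENE", "TYPE"))) {
    abort("inclusion table must start with columns EVENT, GENE, TYPE")
  }
  rest <- hdr[-(1:3)]
  psi_cols <- grep("\\.PSI$", rest, value = TRUE)
  q_cols <- grep("\\.Q$", rest, value = TRUE)
  samples <- sub("\\.PSI$", "", psi_cols)
  if (!setequal(sub("\\.Q$", "", q_cols), samples) ||
      length(rest) != 2 * length(samples)) {
    abort("each sample needs exactly one '<sample>.PSI' and one '<sample>.Q' column")
  }
  if (anyDuplicated(raw$EVENT)) {
    abort(sprintf("duplicate EVENT '%s' at row %d",
                  raw$EVENT[which(duplicated(raw$EVENT))[1]],
                  which(duplicated(raw$EVENT))[1]))
  }
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    purrr::map(samples, function(s) {
      q <- raw[[paste0(s, ".Q")]][i]
      parsed <- parse_q_string(q, lenient = lenient)
      if (is.null(parsed)) {
        abort(sprintf("row %d, column '%s.Q': unparseable quality string '%s'",
                      i, s, q))
      }
      psi_str <- raw[[paste0(s, ".PSI")]][i]
      emp <- if (parsed$raw_inc + parsed$raw_exc > 0) {
        parsed$raw_inc / (parsed$raw_inc + parsed$raw_exc)
      } else NA_real_
      if (!is.na(psi_str) && psi_str != "NA") {
        psi_val <- suppressWarnings(as.numeric(psi_str)) / 100
        if (is.na(psi_val)) {
          abort(sprintf("row %d, column '%s.PSI': not a number ('%s')",
                        i, s, psi_str))
        }
        if (is.na(emp) || abs(psi_val - emp) > 0.005) {
          abort(sprintf(
            "row %d, column '%s.PSI': PSI %s inconsistent with counts %d,%d",
            i, s, psi_str, parsed$inc, parsed$exc))
        }
      } else if (!is.na(emp)) {
        abort(sprintf(
          "row %d, column '%s.PSI': NA but counts %d,%d define a PSI",
          i, s, parsed$inc, parsed$exc))
      }
      tibble::tibble(event_id = raw$EVENT[i], gene_id = raw$GENE[i],
                     event_type = raw$TYPE[i], sample_id = s,
                     inc = parsed$inc, exc = parsed$exc,
                     coverage = parsed$score)
    }) |> purrr::list_rbind()
  })
  splice_events(purrr::list_rbind(rows))
}

#' Write a splicing-event inclusion table
#'
#' Inverse of [read_inclusion_table()]: one row per event, PSI rendered as a
#' percentage with 2 decimals (or `NA`), quality strings as `SCORE@inc,exc`.
#' Rows are ordered by event id, samples by their order in the table, so
#' output is byte-deterministic.
#'
#' @param events A `splice_events` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inclusion_table <- function(events, path) {
  samples <- unique(events$sample_id)
  wide <- events |>
    dplyr::mutate(
      PSI = fmt_pct(.data$psi),
      Q = sprintf("%s@%d,%d", as.character(.data$coverage), .data$inc,
                  .data$exc)
    ) |>
    dplyr::select("event_id", "gene_id", "event_type", "sample_id", "PSI",
                  "Q") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = c("PSI", "Q"),
                       names_glue = "{sample_id}.{.value}") |>
    dplyr::arrange(.data$event_id)
  ordered_cols <- c("event_id", "gene_id", "event_type",
                    as.vector(rbind(paste0(samples, ".PSI"),
                                    paste0(samples, ".Q"))))
  wide <- wide[ordered_cols]
  names(wide)[1:3] <- c("EVENT", "GENE", "TYPE")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a sample-to-condition design table
#'
#' Two-column TSV (`sample_id`, `condition`) mapping each sample to one of
#' exactly two conditions.
#'
#' @param path Path to the TSV file.
#' @param reference Reference condition label (defaults to the first in
#'   sorted order).
#' @return A `study_design` tibble.
#' @export
read_design <- function(path, reference = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(df) == 0) abort("design file is empty")
  study_design(df, reference = reference)
}

#' Write per-event differential results
#'
#' TSV with stable column order `event_id`, `event_type`,
#' `psi_control_pct`, `psi_knockdown_pct`, `delta_psi_pct`, `prob_positive`,
#' `prob_differential`, `significant`; PSIs and delta-PSI as percentages with
#' 2 decimals, probabilities with 4 decimals, rows ordered by event id.
#'
#' @param results Per-event results tibble or a `diffsplice_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "diffsplice_fit")) results <- results$results
  out <- results |>
    dplyr::arrange(.data$event_id) |>
    dplyr::transmute(
      event_id = .data$event_id,
      event_type = as.character(.data$event_type),
      psi_control_pct = fmt_pct(.data$psi_control),
      psi_knockdown_pct = fmt_pct(.data$psi_knockdown),
      delta_psi_pct = fmt_pct(.data$delta_psi),
      prob_positive = fmt_num(.data$prob_positive),
      prob_differential = fmt_num(.data$prob_differential),
      significant = .data$significant
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read per-event differential results back from TSV
#'
#' Inverse of [write_results()] up to the documented rounding; percentages
#' are converted back to fractions.
#'
#' @param path Path written by [write_results()].
#' @return Tibble with the same columns as a fit's `results`.
#' @export
read_results <- function(path) {
  df <- readr::read_tsv(path, col_types = "cccccccl", progress = FALSE)
  tibble::tibble(
    event_id = df$event_id,
    event_type = factor(df$event_type, levels = event_types()),
    psi_control = as.numeric(df$psi_control_pct) / 100,
    psi_knockdown = as.numeric(df$psi_knockdown_pct) / 100,
    delta_psi = as.numeric(df$delta_psi_pct) / 100,
    prob_positive = as.numeric(df$prob_positive),
    prob_differential = as.numeric(df$prob_differential),
    significant = df$significant
  )
}

#' Write per-event-type direction summaries
#'
#' TSV with columns `event_type`, `n_positive`, `n_total`, `proportion_pct`,
#' `chi2`, `p_value`, `ci_low_pct`, `ci_high_pct`, `conf_level`.
#'
#' @param summaries A `direction_summary` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_direction_summary <- function(summaries, path) {
  out <- summaries |>
    dplyr::transmute(
      event_type = as.character(.data$event_type),
      n_positive = .data$n_positive,
      n_total = .data$n_total,
      proportion_pct = fmt_num(.data$proportion_pct, 2),
      chi2 = fmt_num(.data$chi2, 4),
      p_value = ifelse(is.na(.data$p_value), "NA",
                       sprintf("%.6g", .data$p_value)),
      ci_low_pct = fmt_pct(.data$ci_low),
      ci_high_pct = fmt_pct(.data$ci_high),
      conf_level = .data$conf_level
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write the simulation truth table
#'
#' @param truth Truth tibble from [simulate_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  out <- truth |>
    dplyr::mutate(
      event_type = as.character(.data$event_type),
      dplyr::across(c("true_psi_control", "true_psi_knockdown", "true_delta"),
                    ~ sprintf("%.6f", .x))
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
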