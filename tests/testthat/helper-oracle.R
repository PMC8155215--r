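# Independent numeric oracle for P(X > Y), X ~ Beta(a1, b1), Y ~ Beta(a2, b2),
# by double integration: P(X > Y) = integral of f_X(x) * F_Y(x) dx.
beta_gt_prob <- function(a1, b1, a2, b2) {
  stats::integrate(function(x) stats::dbeta(x, a1, b1) *
                     stats::pbeta(x, a2, b2),
                   0, 1, rel.tol = 1e-10)$value
}

# Minimal long-form event table builder for unit tests.
make_event <- function(event_id = "EV1", gene = "geneA", type = "ES",
                       inc, exc, coverage = NULL,
                       sample_ids = paste0("s", seq_along(inc))) {
  if (is.null(coverage)) coverage <- rep("OK", length(inc))
  splice_events(tibble::tibble(
    event_id = event_id, gene_id = gene, event_type = type,
    sample_id = sample_ids, inc = inc, exc = exc, coverage = coverage
  ))
}

make_design <- function(n_ctrl = 1, n_kd = 1) {
  study_design(tibble::tibble(
    sample_id = c(paste0("s", seq_len(n_ctrl)),
                  paste0("s", n_ctrl + seq_len(n_kd))),
    condition = rep(c("control", "knockdown"), c(n_ctrl, n_kd))
  ), reference = "control")
}

# Results tibble with planted direction counts for one event type:
# n_pos positive calls out of n_total significant calls.
planted_results <- function(event_type, n_pos, n_total) {
  tibble::tibble(
    event_id = sprintf("%s%05d", event_type, seq_len(n_total)),
    event_type = event_type,
    delta_psi = rep(c(0.2, -0.2), c(n_pos, n_total - n_pos)),
    significant = TRUE
  )
}
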