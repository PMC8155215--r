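test_that("emissions draw from Beta(inc+1, exc+1) with the requested length", {
  set.seed(1)
  e <- emit_psi(0, 0, 500)
  expect_length(e, 500)
  expect_true(all(e > 0 & e < 1))
  # Beta(1,1) is uniform: mean 0.5, sd 1/sqrt(12)
  expect_lt(abs(mean(e) - 0.5), 3 / sqrt(12 * 500))
  e2 <- emit_psi(10, 30, 20000)
  se <- sqrt(11 * 31 / (42^2 * 43)) / sqrt(20000)
  expect_lt(abs(mean(e2) - 11 / 42), 3 * se)
  expect_error(emit_psi(1, 1, 0), "positive integer")
  set.seed(9); a <- emit_psi(3, 4, 100)
  set.seed(9); b <- emit_psi(3, 4, 100)
  expect_identical(a, b)
})

test_that("pooling concatenates n_emit draws per replicate per condition", {
  ev <- make_event(inc = rep(5, 5), exc = rep(5, 5))
  des <- make_design(n_ctrl = 3, n_kd = 2)
  set.seed(4)
  pooled <- pooled_condition_values(ev, des, n_emit = 500)
  expect_named(pooled, c("control", "knockdown"))
  expect_length(pooled$control, 1500)
  expect_length(pooled$knockdown, 1000)
  # single replicate: the pooled vector is exactly that sample's emission
  ev1 <- make_event(inc = c(7, 2), exc = c(3, 8))
  des1 <- make_design(1, 1)
  set.seed(5)
  p1 <- pooled_condition_values(ev1, des1, n_emit = 200)
  set.seed(5)
  expect_identical(p1$control, emit_psi(7, 3, 200))
  # sample not in design is a configuration error
  expect_error(
    pooled_condition_values(
      make_event(inc = 1, exc = 1, sample_ids = "ghost"), des1, 10),
    "not in the design"
  )
})

test_that("condition PSI is the median of pooled emissions", {
  expect_equal(condition_psi(c(0.2, 0.4, 0.9)), 0.4)
  expect_equal(condition_psi(c(0.2, 0.4, 0.6, 0.9)), 0.5)
  expect_error(condition_psi(numeric()), "empty")
  set.seed(2)
  pooled <- emit_psi(5, 5, 20000)
  expect_lt(abs(condition_psi(pooled) - 0.5), 3 * sqrt(0.25 / 20000))
})

test_that("prob_positive matches the exact beta exceedance probability", {
  set.seed(10)
  # exchangeable inputs force 1/2
  p_null <- prob_positive(emit_psi(5, 5, 20000), emit_psi(5, 5, 20000))
  expect_lt(abs(p_null - 0.5), 3 * sqrt(0.25 / 20000))
  # (inc=2,exc=1) vs (1,2): exact P(Beta(3,2) > Beta(2,3)) = 53/70
  p <- prob_positive(emit_psi(2, 1, 20000), emit_psi(1, 2, 20000))
  oracle <- beta_gt_prob(3, 2, 2, 3)
  expect_equal(oracle, 53 / 70, tolerance = 1e-8)
  expect_lt(abs(p - oracle), 3 * sqrt(oracle * (1 - oracle) / 20000))
  # fully separated counts
  p_sep <- prob_positive(emit_psi(50, 0, 20000), emit_psi(0, 50, 20000))
  expect_gte(p_sep, 0.999)
  expect_error(prob_positive(numeric(), runif(5)), "non-empty")
})

test_that("swapping conditions complements the direction probability", {
  set.seed(11)
  for (i in 1:5) {
    kd <- emit_psi(8, 4, 20000)
    ctrl <- emit_psi(4, 8, 20000)
    p <- prob_positive(kd, ctrl)
    q <- prob_positive(ctrl, kd)
    expect_lt(abs(p - (1 - q)), 3 * sqrt(0.25 / 20000) * 2)
  }
})

test_that("exact exceedance probability is monotone in the inclusion count", {
  oracle <- vapply(0:15, function(i) beta_gt_prob(i + 1, 5, 3, 3), 0)
  expect_true(all(diff(oracle) > 0))
})

test_that("a call requires both strict threshold exceedances", {
  des <- make_design(3, 3)
  # clearly separated, deep counts: must be called
  ev_hi <- make_event(inc = c(10, 12, 11, 80, 82, 81),
                      exc = c(90, 88, 89, 20, 18, 19))
  r_hi <- differential_event(ev_hi, des, seed = 1)
  expect_true(r_hi$significant)
  expect_gt(r_hi$delta_psi, 0.5)
  # identical conditions: must not be called
  ev_null <- make_event(inc = rep(50, 6), exc = rep(50, 6))
  r_null <- differential_event(ev_null, des, seed = 1)
  expect_false(r_null$significant)
  # large effect but tiny coverage: probability cannot clear 0.8
  ev_shallow <- make_event(inc = c(0, 0, 0, 1, 1, 1),
                           exc = c(1, 1, 1, 0, 0, 0))
  r_sh <- differential_event(ev_shallow, des, seed = 1)
  expect_identical(r_sh$significant,
                   r_sh$prob_differential > 0.8 & abs(r_sh$delta_psi) > 0.05)
  # invariants of the result record
  for (r in list(r_hi, r_null, r_sh)) {
    expect_equal(r$delta_psi, r$psi_knockdown - r$psi_control)
    expect_equal(r$prob_differential,
                 max(r$prob_positive, 1 - r$prob_positive))
  }
})

test_that("threshold configuration is validated", {
  expect_error(call_thresholds(prob_threshold = 1.2), "0.5, 1")
  expect_error(call_thresholds(prob_threshold = 0.4), "0.5, 1")
  expect_error(call_thresholds(dpsi_threshold = 0), "0, 1")
  expect_error(call_thresholds(n_emit = -5), "positive integer")
})

test_that("the runner is deterministic and order-independent", {
  sim <- simulate_dataset(sim_config(
    n_events_per_type = c(ES = 15, IR = 15, Alt5 = 0, Alt3 = 0), seed = 3))
  fit1 <- run_differential(sim$events, sim$design, seed = 99)
  fit2 <- run_differential(sim$events, sim$design, seed = 99)
  expect_identical(fit1$results, fit2$results)
  # shuffled event rows: identical results (per-event substreams)
  set.seed(1)
  shuffled <- sim$events[sample(nrow(sim$events)), ]
  fit3 <- run_differential(shuffled, sim$design, seed = 99)
  expect_identical(fit1$results, fit3$results)
  # a different master seed perturbs the emissions
  fit4 <- run_differential(sim$events, sim$design, seed = 100)
  expect_false(identical(fit1$results$prob_positive,
                         fit4$results$prob_positive))
  # no call may sit at or below either threshold
  res <- fit1$results
  called <- res[res$significant, ]
  expect_true(all(called$prob_differential > 0.8))
  expect_true(all(abs(called$delta_psi) > 0.05))
  expect_true(all(res$prob_differential >= 0.5 & res$prob_differential <= 1))
})

test_that("the runner filters coverage and handles empty input", {
  empty <- make_event(inc = 1, exc = 1)[0, ]
  des <- make_design(1, 1)
  fit <- run_differential(empty, des, seed = 1)
  expect_equal(nrow(fit$results), 0)
  expect_equal(fit$n_dropped_coverage, 0)
  # one event below the coverage floor is dropped and counted
  ev <- dplyr::bind_rows(
    make_event("EV1", inc = c(50, 50), exc = c(50, 50)),
    make_event("EV2", inc = c(50, 3), exc = c(50, 3),
               coverage = c("OK", "N"))
  )
  fit2 <- run_differential(splice_events(ev), des, seed = 1)
  expect_equal(fit2$n_input, 2)
  expect_equal(fit2$n_dropped_coverage, 1)
  expect_equal(fit2$results$event_id, "EV1")
  g <- glance(fit2)
  expect_equal(g$n_tested, 1)
  expect_identical(tidy(fit2), fit2$results)
  expect_error(run_differential(ev, des), "seed")
})
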