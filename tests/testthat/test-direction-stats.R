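test_that("direction counts tally positive calls among significant events", {
  res <- tibble::tibble(
    event_id = paste0("e", 1:5),
    event_type = c("IR", "IR", "IR", "ES", "IR"),
    delta_psi = c(0.1, 0.2, -0.1, 0.3, 0.4),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(direction_counts(res, "IR"),
               c(n_positive = 2, n_total = 3))
  expect_equal(direction_counts(res, "Alt5"),
               c(n_positive = 0, n_total = 0))
  expect_error(direction_counts(res, "XX"), "unknown event_type")
})

test_that("corrected proportion test matches the reference implementation", {
  # exact null observation: capped correction gives chi2 = 0, p = 1
  t50 <- proportion_test(50, 100)
  expect_equal(t50$chi2, 0)
  expect_equal(t50$p_value, 1)
  # printed-count case reaches the machine-precision floor
  expect_lte(proportion_test(805, 849)$p_value, 1e-16)
  # agreement with stats::prop.test to 6 significant digits across a grid
  cases <- list(c(805, 849), c(430, 741), c(50, 100), c(3, 10), c(0, 7),
                c(99, 100), c(1, 1), c(250, 500))
  for (kn in cases) {
    mine <- proportion_test(kn[1], kn[2])
    ref <- suppressWarnings(prop.test(kn[1], kn[2], p = 0.5, correct = TRUE))
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
    ci <- proportion_ci(kn[1], kn[2])
    expect_equal(unname(ci), ref$conf.int[1:2], tolerance = 1e-6)
  }
  expect_error(proportion_test(1, 0), "positive integer")
  expect_error(proportion_test(5, 3), "n_total")
})

test_that("the test is two-sided symmetric and monotone in the deviation", {
  for (n in c(20, 101, 849)) {
    k <- round(n * 0.3)
    expect_equal(proportion_test(k, n)$p_value,
                 proportion_test(n - k, n)$p_value)
  }
  p_seq <- vapply(50:100, function(k) proportion_test(k, 100)$p_value, 0)
  expect_true(all(diff(p_seq) <= 1e-12))
})

test_that("Wilson intervals bracket the estimate and clip at the boundary", {
  ci <- proportion_ci(50, 100)
  expect_equal(unname(ci["ci_low"] + ci["ci_high"]), 1, tolerance = 1e-10)
  expect_equal(unname(proportion_ci(0, 10)["ci_low"]), 0)
  expect_equal(unname(proportion_ci(10, 10)["ci_high"]), 1)
  for (kn in list(c(805, 849), c(7, 30))) {
    ci <- proportion_ci(kn[1], kn[2])
    expect_true(ci["ci_low"] <= kn[1] / kn[2] &&
                  kn[1] / kn[2] <= ci["ci_high"])
    expect_true(ci["ci_low"] >= 0 && ci["ci_high"] <= 1)
  }
})

test_that("null rejection rate matches exact corrected-test calibration", {
  # exact rejection probability of the corrected test under a fair coin,
  # by full binomial enumeration (independent of the implementation path)
  n <- 100
  rejects <- vapply(0:n, function(k) proportion_test(k, n)$p_value < 0.05,
                    logical(1))
  exact_rate <- sum(dbinom(0:n, n, 0.5)[rejects])
  # the continuity correction makes the test conservative at this n
  expect_lte(exact_rate, 0.05)
  expect_gte(exact_rate, 0.02)
  set.seed(7)
  k_draws <- rbinom(2000, n, 0.5)
  emp_rate <- mean(vapply(k_draws,
                          function(k) proportion_test(k, n)$p_value < 0.05,
                          logical(1)))
  se <- sqrt(exact_rate * (1 - exact_rate) / 2000)
  expect_lt(abs(emp_rate - exact_rate), 3 * se)
})

test_that("the 95% interval covers a true proportion at close to 95%", {
  set.seed(8)
  k_draws <- rbinom(2000, 100, 0.7)
  covered <- vapply(k_draws, function(k) {
    ci <- proportion_ci(k, 100)
    ci["ci_low"] <= 0.7 && 0.7 <= ci["ci_high"]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("direction summaries reproduce planted printed proportions", {
  res <- dplyr::bind_rows(planted_results("IR", 805, 849),
                          planted_results("ES", 430, 741))
  s <- summarize_directions(res)
  expect_s3_class(s, "direction_summary")
  expect_equal(s$proportion_pct[s$event_type == "IR"], 94.82)
  expect_equal(s$proportion_pct[s$event_type == "ES"], 58.03)
  expect_true(all(s$ci_low <= s$proportion & s$proportion <= s$ci_high))
})

test_that("types with no significant events are reported, not dropped", {
  res <- dplyr::bind_rows(
    planted_results("IR", 2, 3),
    tibble::tibble(event_id = "x1", event_type = "ES",
                   delta_psi = 0.2, significant = FALSE)
  )
  s <- summarize_directions(res)
  expect_setequal(s$event_type, c("ES", "IR"))
  es <- s[s$event_type == "ES", ]
  expect_equal(es$n_total, 0L)
  expect_true(is.na(es$p_value) && is.na(es$proportion))
  # a single-type input yields a single row
  s_ir <- summarize_directions(planted_results("IR", 3, 4))
  expect_equal(nrow(s_ir), 1)
})
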