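test_that("effective degrees of freedom match the printed accuracy table", {
  expect_equal(satterthwaite_df(2.29, 0.14, 8, 3, 3), 10.78,
               tolerance = 1e-2 / 10)
  expect_equal(satterthwaite_df(1.61, 1.67, 8, 3, 3), 6.02,
               tolerance = 1e-2)
  expect_equal(satterthwaite_df(1.35, 1.48, 8, 3, 3), 5.77,
               tolerance = 1e-2)
  # truncated between component: df falls back to the within df
  expect_equal(satterthwaite_df(3.09, 0, 8, 3, 3), 8)
  # single-assay level floors at 3
  expect_equal(satterthwaite_df(2.16, 0, 2, 0, 3), 3)
  expect_error(satterthwaite_df(2, 1, 8, 3, m_h = 1), "m_h")
})

test_that("the coverage factor is the two-sided t quantile", {
  expect_equal(coverage_factor(8, 0.95), 2.306, tolerance = 1e-3)
  expect_gt(coverage_factor(8, 0.99), coverage_factor(8, 0.95))
  expect_lt(coverage_factor(20, 0.95), coverage_factor(5, 0.95))
})

test_that("beta-expectation intervals reproduce the printed bounds", {
  ti <- beta_expectation_ti(-19.01, 2.72, 8)
  expect_equal(ti$lower, -25.28, tolerance = 1e-2 / 5)
  expect_equal(ti$upper, -12.74, tolerance = 1e-2 / 5)
  ti50 <- beta_expectation_ti(-16.66, 2.54, 8)
  expect_equal(ti50$lower, -22.52, tolerance = 1e-2 / 5)
  degenerate <- beta_expectation_ti(-10, 0, 8)
  expect_equal(c(degenerate$lower, degenerate$upper), c(-10, -10))
})

test_that("acceptance decisions use closed bounds", {
  expect_true(acceptance_decision(-25.28, -12.74, 30))
  expect_false(acceptance_decision(-31, -10, 30))
  expect_true(acceptance_decision(-30, 30, 30))
  ti <- beta_expectation_ti(-19.01, 2.72, 8)
  expect_true(acceptance_decision(ti, limit = 30))
})

test_that("the validated range requires contiguous passing levels", {
  spikes <- seq(20, 80, 10)
  all_pass <- validated_range(rep(TRUE, 7), spikes)
  expect_equal(all_pass$lower, 20)
  expect_equal(all_pass$upper, 80)
  expect_equal(all_pass$lloq, 20)
  top3 <- validated_range(c(rep(FALSE, 4), rep(TRUE, 3)), spikes)
  expect_equal(top3$lloq, 60)
  expect_warning(frag <- validated_range(c(TRUE, FALSE, TRUE), c(20, 30, 40)),
                 "fragmented")
  expect_true(frag$fragmented)
  expect_true(is.na(frag$lloq))
  none <- validated_range(rep(FALSE, 3), c(20, 30, 40))
  expect_true(is.na(none$lloq))
})

test_that("content intervals degenerate to the bias on zero-variance data", {
  blocks <- expand.grid(assay = 1:3, spike_ng = c(20, 50, 80),
                        block = 1:3)
  blocks$y_ng <- 0.85 * blocks$spike_ng
  blocks <- relative_errors(blocks)
  ct <- content_ti_95_95(blocks, B = 100, M = 100, seed = 1)
  expect_equal(ct$hw, rep(0, 3), tolerance = 1e-12)
  expect_equal(ct$lower, ct$bias)
})

test_that("content intervals are deterministic under a fixed seed", {
  b <- gen_replicate_blocks(seed = 41)
  c1 <- content_ti_95_95(b, B = 150, M = 150, seed = 4)
  c2 <- content_ti_95_95(b, B = 150, M = 150, seed = 4)
  expect_identical(c1, c2)
  expect_error(content_ti_95_95(b[b$assay == 1, ], B = 150, M = 150),
               ">= 2 assays")
  expect_error(content_ti_95_95(b, B = 50, M = 500), ">= 100")
})

test_that("large-sample content half-widths respect the sanity floor", {
  des <- validation_design(spike_ng = c(20, 50, 80),
                           assay_levels = rep(list(1:3), 10),
                           preparations = 20)
  truth <- paper_truth()
  b <- gen_replicate_blocks(des, truth, seed = 42)
  ct <- content_ti_95_95(b, B = 300, M = 300, seed = 5)
  sigma_true <- sqrt(truth$sigma_W^2 + truth$sigma_B^2) *
    truth_re_scale(truth, ct$spike_ng)
  expect_true(all(ct$hw >= 1.645 * sigma_true * 0.9))
  # and not absurdly wide either: below 2x the nominal content width
  expect_true(all(ct$hw <= 2 * 1.96 * sigma_true))
})
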