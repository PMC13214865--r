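test_that("relative errors reproduce the printed trueness values", {
  b <- data.frame(y_ng = 64.79, spike_ng = 80)
  expect_equal(relative_errors(b)$re, -19.01, tolerance = 5e-3 / 19)
  expect_equal(100 + relative_errors(b)$re, 80.99, tolerance = 5e-3 / 80)
})

test_that("identical values give null variance components", {
  st <- anova_mom(rep(-15, 12), rep(1:4, each = 3))
  expect_equal(st$sigma_W, 0)
  expect_equal(st$sigma_B, 0)
  expect_equal(st$sigma_T, 0)
  expect_equal(st$bias, -15)
})

test_that("mean squares match a from-scratch sums-of-squares oracle", {
  set.seed(31)
  re <- rnorm(12, -15, 2)
  assay <- rep(1:4, each = 3)
  st <- anova_mom(re, assay)
  or <- oracle_anova(re, assay)
  expect_equal(st$ms_within, or$ms_within, tolerance = 1e-12)
  expect_equal(st$ms_between, or$ms_between, tolerance = 1e-12)
  # unbalanced groups
  re2 <- rnorm(10); assay2 <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3)
  st2 <- anova_mom(re2, assay2)
  or2 <- oracle_anova(re2, assay2)
  expect_equal(st2$ms_within, or2$ms_within, tolerance = 1e-12)
  expect_equal(st2$ms_between, or2$ms_between, tolerance = 1e-12)
  expect_equal(st2$m_h, 3 / (1/3 + 1/2 + 1/5), tolerance = 1e-12)
})

test_that("total SD composes the printed components", {
  expect_equal(sqrt(1.61^2 + 1.67^2), 2.32, tolerance = 5e-3)
  set.seed(32)
  for (i in 1:20) {
    st <- anova_mom(rnorm(12, 0, 3), rep(1:4, each = 3))
    expect_equal(st$sigma_T, sqrt(st$sigma_W^2 + st$sigma_B^2),
                 tolerance = 1e-12)
    expect_gte(st$sigma_T, max(st$sigma_W, st$sigma_B))
  }
})

test_that("the between component truncates at zero with a flag", {
  # groups identical in mean, spread within: MS_between < MS_within
  re <- c(-1, 0, 1, -1, 0, 1, -1, 0, 1)
  st <- anova_mom(re, rep(1:3, each = 3))
  expect_equal(st$sigma_B, 0)
  expect_true(st$truncated)
  # single assay: between not estimable
  st1 <- anova_mom(c(1, 2, 3), rep(1, 3))
  expect_equal(st1$df_B, 0)
  expect_equal(st1$sigma_B, 0)
  expect_true(st1$truncated)
  expect_error(anova_mom(1, 1), ">= 2")
})

test_that("the log-log variance model reproduces the printed predictions", {
  vm <- fit_variance_model(c(2.30, 2.32, 2.16, 3.09, 0.69, 2.00, 3.81),
                           seq(20, 80, 10), c(12, 12, 3, 12, 3, 12, 12))
  pred <- predict(vm, seq(20, 80, 10))
  expect_equal(pred, c(2.22, 2.36, 2.46, 2.54, 2.61, 2.67, 2.72),
               tolerance = 5e-3 / 2.2)
})

test_that("two levels give an exact fit and predictions are base-invariant", {
  vm <- fit_variance_model(c(2, 4), c(10, 40), c(5, 5))
  expect_equal(predict(vm, c(10, 40)), c(2, 4), tolerance = 1e-12)
  # base-10 refit gives identical predictions
  s <- c(2.3, 3.1, 2.8); mu <- c(20, 40, 80); n <- c(12, 12, 12)
  vm2 <- fit_variance_model(s, mu, n)
  w <- n - 1
  x <- log10(mu); y <- log10(s)
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  b <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  a <- yb - b * xb
  expect_equal(predict(vm2, mu), 10^(a + b * x), tolerance = 1e-12)
})

test_that("zero-SD levels are excluded from the variance model", {
  expect_warning(vm <- fit_variance_model(c(0, 2, 3), c(20, 40, 80),
                                          c(12, 12, 12)), "zero total SD")
  expect_equal(length(vm$mu), 2)
  expect_error(suppressWarnings(fit_variance_model(c(0, 2), c(20, 40),
                                                   c(3, 3))), ">= 2")
})

test_that("level statistics recover generator components on average", {
  truth <- paper_truth()
  set.seed(33)
  comps <- t(vapply(1:300, function(i) {
    b <- gen_replicate_blocks(truth = truth, seed = sample.int(1e7, 1))
    ls <- level_stats(b)
    row <- ls[ls$spike_ng == 50, ]
    c(sw = row$sigma_W, sb = row$sigma_B)
  }, c(sw = 0, sb = 0)))
  scale50 <- truth_re_scale(truth, 50)
  # sigma_W on the RE scale, within 10 % relative of truth
  expect_equal(mean(comps[, "sw"]), truth$sigma_W * scale50,
               tolerance = 0.1)
  # sigma_B is below the design's detectability floor (~1.41 sigma_W at
  # df_B = 3); require only that its average stays under that floor
  expect_lt(mean(comps[, "sb"]), 1.41 * truth$sigma_W * scale50)
})
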