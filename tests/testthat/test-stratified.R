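test_that("strata cut at the 5/25/50/75/100 percentiles", {
  ab <- stats::setNames(as.numeric(1:1000), paste0("P", 1:1000))
  s <- assign_strata(ab)
  expect_equal(length(s$excluded_below_p5), 50)
  sizes <- tabulate(s$stratum, 4)
  expect_equal(sizes[1], 200, tolerance = 1)
  expect_equal(sizes[2], 250, tolerance = 1)
  expect_equal(sizes[3], 250, tolerance = 1)
  expect_equal(sizes[4], 250, tolerance = 1)
  expect_identical(assign_strata(ab), s)  # deterministic
  expect_error(assign_strata(ab[1:50]), ">= 120")
  expect_error(assign_strata(stats::setNames(rep(1, 200),
                                             paste0("P", 1:200))),
               "degenerate")
})

test_that("cell reportables equal the cell mean in expectation", {
  cellv <- rep(3.6, 40)
  expect_equal(as.numeric(bootstrap_reportable(cellv, B = 200, seed = 1)),
               3.6, tolerance = 1e-12)
  small <- bootstrap_reportable(rnorm(29), B = 200, seed = 1)
  expect_true(is.na(small))
  expect_match(attr(small, "reason"), "fewer than 30")
  set.seed(2)
  v <- rlnorm(60, 2, 0.5)
  B <- 2000
  mu <- as.numeric(bootstrap_reportable(v, B = B, seed = 3))
  expect_lt(abs(mu - mean(v)), 3 * sd(v) / sqrt(length(v) * B))
})

test_that("exclusion bookkeeping conserves cells", {
  truth <- synthetic_truth()
  tab <- gen_protein_ppm_table(truth, n_proteins = 140, seed = 61)
  anchor <- tab[tab$level == 4, ]
  ab <- tapply(anchor$ppm, anchor$protein, mean)
  strat <- assign_strata(stats::setNames(as.numeric(ab), names(ab)))
  sc <- stratum_cells(tab, strat, B = 50, seed = 1)
  n_cells <- length(unique(interaction(tab$assay, tab$level, tab$block))) * 4
  expect_equal(nrow(sc$cells) + nrow(sc$excluded), n_cells)
  # with 140 proteins, Q1 holds ~28 proteins and falls below the 30 floor
  expect_true(all(sc$excluded$stratum == 1))
  expect_match(sc$excluded$reason[1], "fewer than 30")
})

test_that("the anchor level has zero mean relative error by construction", {
  tab <- gen_protein_ppm_table(n_proteins = 400, seed = 62)
  st <- stratified_te(tab, B = 100, seed = 2)
  cells <- st$cells
  for (b in unique(cells$stratum)) {
    at_anchor <- cells$re[cells$stratum == b & cells$level == 4]
    expect_equal(mean(at_anchor), 0, tolerance = 1e-9)
  }
})

test_that("noise-free unit calibration passes everywhere with zero bias", {
  truth <- synthetic_truth(sigma_W = 0, sigma_B = 0, protein_noise_sd = 0,
                           stratum_slopes = rep(1, 4),
                           stratum_intercepts = rep(0, 4))
  tab <- gen_protein_ppm_table(truth, n_proteins = 400, seed = 63)
  st <- stratified_te(tab, B = 1000, seed = 3)
  # biases vanish up to the Monte-Carlo noise of the cell bootstrap
  expect_lt(max(abs(st$profile$table$bias)), 1)
  expect_true(all(st$profile$table$pass))
  expect_equal(sort(st$profile$validated_levels), 1:7)
})

test_that("a compressed top stratum shows the positive-to-negative bias transition", {
  tab <- gen_protein_ppm_table(n_proteins = 400, seed = 64)
  st <- stratified_te(tab, B = 100, seed = 4)
  q4 <- st$profile$table[st$profile$table$stratum == 4, ]
  q4 <- q4[order(q4$level), ]
  expect_gt(q4$bias[q4$level == 1], 0)
  expect_lt(q4$bias[q4$level == 7], 0)
})

test_that("stratified calibration recovers the generator slopes", {
  truth <- paper_truth()
  tab <- gen_protein_ppm_table(truth, n_proteins = 600, seed = 65)
  st <- stratified_te(tab, B = 100, seed = 5)
  expect_equal(st$calibration$slope, truth$stratum_slopes, tolerance = 0.05)
})

test_that("a stratum failing a level removes it from the validated domain", {
  cells <- expand.grid(assay = 1:4, level = c(1, 4, 7), block = 1:3,
                       stratum = 1:2)
  cells$spike_ng <- c(20, 50, 80)[match(cells$level, c(1, 4, 7))]
  set.seed(66)
  cells$r_theo <- cells$spike_ng / 50
  cells$re <- rnorm(nrow(cells), 0, 2)
  # stratum 2 grossly biased at the lowest level
  cells$re[cells$stratum == 2 & cells$level == 1] <- 60
  prof <- stratum_accuracy_profile(cells, limit = 35)
  expect_false(1 %in% prof$validated_levels)
  expect_true(all(c(4, 7) %in% prof$validated_levels))
})

test_that("abundance limits use conservative percentiles", {
  cells <- expand.grid(assay = 1:2, level = c(1, 7), block = 1:3,
                       stratum = c(1, 4))
  cells$mu_hat <- 3.6
  lim <- abundance_lloq_uloq(cells, validated_levels = c(1, 7))
  expect_equal(lim$lloq$mean, 3.6)
  expect_equal(lim$lloq$p95, 3.6)
  set.seed(67)
  skew <- rlnorm(200, 1, 0.8)
  cells2 <- data.frame(assay = 1, level = 1, block = 1, stratum = 1,
                       mu_hat = skew)
  cells2 <- rbind(cells2,
                  within(cells2, { stratum <- 4; level <- 7 }))
  lim2 <- abundance_lloq_uloq(cells2, validated_levels = c(1, 7))
  expect_gte(lim2$lloq$p95, lim2$lloq$mean)   # right-skewed: P95 >= mean
  expect_lte(lim2$uloq$p05, lim2$uloq$mean)
  expect_error(abundance_lloq_uloq(cells2, integer(0)), "empty")
})
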