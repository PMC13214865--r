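test_that("TIC normalization equalises run totals at the median", {
  obs <- data.frame(run_id = rep(c("r1", "r2", "r3"), each = 2),
                    intensity = c(40, 60, 120, 80, 150, 150))
  out <- tic_normalize(obs)
  totals <- as.numeric(tapply(out$intensity, out$run_id, sum))
  expect_equal(totals, rep(200, 3))
  # within-run ratios preserved
  expect_equal(out$intensity[1] / out$intensity[2], 40 / 60)
  # already-equal totals unchanged
  eq <- data.frame(run_id = c("a", "b"), intensity = c(100, 100))
  expect_equal(tic_normalize(eq)$intensity, c(100, 100))
  zero <- data.frame(run_id = c("a", "b"), intensity = c(0, 10))
  expect_error(tic_normalize(zero), "zero total")
})

test_that("modified Z-score filter removes gross outliers only", {
  expect_equal(as.numeric(modified_zscore_filter(c(1, 2, 3, 4, 100))),
               c(1, 2, 3, 4))
  expect_equal(round(modified_zscore(c(1, 2, 3, 4, 100))[5], 1), 65.4)
  expect_equal(as.numeric(modified_zscore_filter(c(5, 5, 5, 5))),
               c(5, 5, 5, 5))
  expect_equal(as.numeric(modified_zscore_filter(c(1, 2, 3))), c(1, 2, 3))
  short <- modified_zscore_filter(c(1, 100))
  expect_equal(as.numeric(short), c(1, 100))
  expect_false(attr(short, "filtered"))
  # zero-MAD fallback to scaled mean absolute deviation
  expect_lt(length(modified_zscore_filter(c(rep(1, 9), 50))), 10)
})

test_that("replicate CV filter applies the percent cutoff", {
  expect_true(cv_filter(c(7, 7, 7)))
  expect_false(cv_filter(c(100, 200)))   # CV ~47.1 %
  expect_true(cv_filter(c(100, 101, 99)))  # CV 1 %
  expect_false(cv_filter(c(-1, 1)))      # zero mean
  expect_error(cv_filter(5), ">= 2")
})

test_that("response factor is the median intensity per fmol", {
  expect_equal(response_factor(c(100, 200, 300), c(1, 2, 3))$rf, 100)
  expect_equal(response_factor(c(90, 100, 110, 200), c(1, 1, 1, 1))$rf, 105)
  expect_equal(response_factor(500, 5)$rf, 100)
  expect_error(response_factor(numeric(0), numeric(0)), "at least one")
  expect_error(response_factor(10, 0), "> 0")
})

test_that("average molecular weight uses standard residue masses", {
  expect_equal(compute_mw("G"), 75.07, tolerance = 0.01)
  expect_equal(compute_mw("GG"), 132.12, tolerance = 0.01)
  expect_error(compute_mw(""), "empty")
  expect_error(compute_mw("GXZ"), "unknown residue")
})

test_that("Hi3 mass follows the top-3 conversion", {
  expect_equal(hi3_protein_mass(c(a = 500, b = 300, c = 200),
                                rf = 100, mw = 50000), 0.5)
  expect_equal(hi3_protein_mass(c(a = 0, b = 0, c = 0), 100, 50000), 0)
  # doubling intensities doubles the mass
  base <- c(a = 10, b = 20, c = 30, d = 40)
  expect_equal(hi3_protein_mass(base * 2, 50, 1e4),
               2 * hi3_protein_mass(base, 50, 1e4))
  expect_error(hi3_protein_mass(c(a = 1, b = 2), 100, 1000), ">= 3")
})

test_that("total HCP sums group masses and converts to ppm", {
  expect_equal(total_hcp(c(0.5, 0.25)), 0.75)
  expect_equal(total_hcp(numeric(0)), 0)
  expect_equal(to_ppm(50, 0.5), 100)
  expect_error(to_ppm(1, 0), "> 0")
  # additivity over any partition
  set.seed(3)
  m <- runif(10)
  expect_equal(total_hcp(m[1:4]) + total_hcp(m[5:10]), total_hcp(m))
})

test_that("the noiseless pipeline returns each protein's true mass", {
  prot <- data.frame(accession = c("A", "B", "C"),
                     mw = c(2e4, 5e4, 1e5),
                     fmol = c(10, 2, 0.5), n_peptides = c(5, 4, 3))
  tab <- gen_peptide_table(prot, rf = 100, seed = 11)
  mw_map <- stats::setNames(prot$mw, prot$accession)
  out <- hi3_quantify(tab, rf = 100, mw_map = mw_map)
  truth_ng <- prot$fmol * prot$mw * 1e-6
  got <- out$proteins$mass_ng[match(prot$accession,
                                    out$proteins$accession)]
  expect_equal(got, truth_ng, tolerance = 1e-9)
  expect_equal(out$total_ng, sum(truth_ng), tolerance = 1e-9)
})

test_that("the filter chain removes most injected outliers", {
  prot <- data.frame(accession = paste0("P", 1:8),
                     mw = rep(3e4, 8), fmol = runif(8, 1, 10),
                     n_peptides = rep(5, 8))
  removed <- vapply(1:50, function(s) {
    tab <- gen_peptide_table(prot, rf = 100, noise_cv = 3,
                             outlier_rate = 0.05, seed = s)
    out <- hi3_quantify(tab, rf = 100,
                        mw_map = stats::setNames(prot$mw, prot$accession))
    kept <- out$filtered
    n_out <- sum(tab$is_outlier)
    if (n_out == 0) return(NA_real_)
    1 - sum(kept$is_outlier) / n_out
  }, numeric(1))
  expect_gte(mean(removed, na.rm = TRUE), 0.9)
})

test_that("single-hit peptides are excluded before quantification", {
  prot <- data.frame(accession = "A", mw = 1e4, fmol = 5, n_peptides = 4)
  tab <- gen_peptide_table(prot, rf = 100, seed = 12)
  # force one peptide down to a single injection
  victim <- tab$sequence[1]
  tab <- tab[!(tab$sequence == victim & tab$run_id != "run1"), ]
  out <- hi3_quantify(tab, rf = 100, mw_map = c(A = 1e4))
  expect_false(victim %in% out$filtered$sequence)
})

test_that("applying the filter chain twice changes nothing more", {
  prot <- data.frame(accession = paste0("P", 1:5), mw = rep(3e4, 5),
                     fmol = runif(5, 1, 10), n_peptides = rep(5, 5))
  tab <- gen_peptide_table(prot, rf = 100, noise_cv = 2,
                           outlier_rate = 0.05, seed = 13)
  mw_map <- stats::setNames(prot$mw, prot$accession)
  once <- hi3_quantify(tab, rf = 100, mw_map = mw_map)
  twice <- hi3_quantify(once$filtered, rf = 100, mw_map = mw_map)
  key <- function(d) sort(paste(d$sequence, d$run_id))
  expect_identical(key(twice$filtered), key(once$filtered))
})

test_that("groups without three quantifiable peptides carry a reason code", {
  prot <- data.frame(accession = "A", mw = 1e4, fmol = 5, n_peptides = 3)
  tab <- gen_peptide_table(prot, rf = 100, seed = 14)
  tab <- tab[tab$sequence != tab$sequence[1], ]  # drop one peptide entirely
  out <- hi3_quantify(tab, rf = 100, mw_map = c(A = 1e4))
  expect_equal(nrow(out$proteins), 0)
  expect_match(out$excluded$reason, "fewer than 3")
})
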