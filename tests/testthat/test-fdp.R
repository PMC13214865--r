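test_that("the scaled entrapment estimator matches its closed form", {
  peps <- data.frame(sequence = paste0("s", 1:2000),
                     label = rep(c("target", "entrapment"),
                                 times = c(1995, 5)),
                     q_value = c(rep(0.005, 995), rep(0.5, 1000),
                                 rep(0.005, 5)))
  # N_E = 5, N_D = 1000 at tau = 0.01
  expect_equal(fdp_estimate(peps, 0.01, r = 1), 0.01)
  expect_equal(fdp_estimate(peps, 0.01, r = 0.5), 0.015)
  none <- peps[peps$label == "target", ]
  expect_equal(fdp_estimate(none, 0.01, r = 1), 0)
  empty <- peps[0, ]
  expect_equal(fdp_estimate(empty, 0.01), 0)
})

test_that("PSM collapse keeps the minimum q-value per sequence", {
  psm <- data.frame(sequence = c("AAK", "AAK", "BBK", "CCK"),
                    q_value = c(0.02, 0.005, 0.1, 0.2),
                    label = c("target", "target", "entrapment", "target"))
  out <- collapse_to_peptides(psm)
  expect_equal(nrow(out), 3)
  expect_equal(out$q_value[out$sequence == "AAK"], 0.005)
  bad <- data.frame(sequence = c("AAK", "AAK"), q_value = c(0.1, 0.2),
                    label = c("target", "entrapment"))
  expect_error(collapse_to_peptides(bad), "conflicting")
})

test_that("foreign entrapment trimming is an exact set difference", {
  expect_setequal(trim_foreign_entrapment(c("A", "B"), c("C", "D")),
                  c("A", "B"))
  expect_equal(trim_foreign_entrapment(c("A", "B"), c("A", "B", "C")),
               character(0))
  f <- c("A", "B", "C", "D"); t <- c("B", "D", "E")
  out <- trim_foreign_entrapment(f, t)
  expect_equal(length(out), length(unique(f)) - length(intersect(f, t)))
})

test_that("shuffled entrapment preserves composition and the C-terminus", {
  tgt <- c("PEPTIDEK", "ELVISLIVESR", "AK")
  res <- build_shuffled_entrapment(tgt, seed = 3)
  expect_true("AK" %in% res$dropped)  # only permutation equals the target
  for (e in res$entrapment) {
    expect_false(e %in% tgt)
    src <- tgt[vapply(tgt, function(t)
      nchar(t) == nchar(e) &&
        identical(sort(strsplit(t, "")[[1]]), sort(strsplit(e, "")[[1]])),
      logical(1))]
    expect_equal(length(src), 1)
    expect_equal(substr(e, nchar(e), nchar(e)),
                 substr(src, nchar(src), nchar(src)))
  }
  expect_identical(build_shuffled_entrapment(tgt, seed = 3),
                   build_shuffled_entrapment(tgt, seed = 3))
  expect_equal(res$r, length(res$entrapment) / length(tgt))
})

test_that("FDP curve counts are nondecreasing in the threshold", {
  sc <- gen_entrapment_scores(n_target = 3000, seed = 21)
  grid <- c(0.001, 0.005, 0.01, 0.05, 0.2, 1)
  curve <- fdp_curve(sc, grid)
  expect_true(all(diff(curve$n_e) >= 0))
  expect_true(all(diff(curve$n_d) >= 0))
  expect_true(all(curve$n_e <= curve$n_d))
  expect_true(all(curve$fdp >= 0))
})

test_that("bootstrap bands behave at the degenerate and generic cases", {
  clean <- data.frame(sequence = paste0("s", 1:500),
                      label = "target", q_value = runif(500, 0, 0.005))
  bands <- bootstrap_fdp_bands(clean, c(0.001, 0.01), B = 200, seed = 1)
  expect_equal(bands$lower, c(0, 0))
  expect_equal(bands$upper, c(0, 0))
  sc <- gen_entrapment_scores(n_target = 4000, seed = 22)
  b1 <- bootstrap_fdp_bands(sc, c(0.005, 0.01, 0.02), B = 300, seed = 9)
  expect_identical(b1, bootstrap_fdp_bands(sc, c(0.005, 0.01, 0.02),
                                           B = 300, seed = 9))
  # pointwise bands contain the point estimate
  expect_true(all(b1$lower <= b1$fdp & b1$fdp <= b1$upper))
  expect_error(bootstrap_fdp_bands(sc, 0.01, B = 50), ">= 200")
})

test_that("the Wilson interval matches the textbook formula and scales", {
  expect_equal(wilson_interval(0, 100)[1], 0)
  got <- wilson_interval(10, 100)
  expect_equal(got, c(0.0552, 0.1744), tolerance = 5e-4)
  expect_equal(wilson_interval(10, 100, scale_factor = 2), 2 * got,
               tolerance = 1e-12)
  expect_error(wilson_interval(0, 0), "> 0")
})

test_that("protein-level propagation is the k-th power of peptide FDP", {
  expect_equal(protein_level_fdp(0.009, 3), 7.29e-7)
  expect_lt(protein_level_fdp(0.009, 3), 1e-6)  # order 1e-7
  expect_equal(protein_level_fdp(0, 5), 0)
  expect_equal(protein_level_fdp(0.3, 1), 0.3)
})
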