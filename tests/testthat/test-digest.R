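test_that("tryptic digestion follows the cleavage rule and length bounds", {
  got <- theoretical_digest("AAKBBRCC", digest_spec(1, 2, 10))
  expect_setequal(got, c("AAK", "BBR", "CC", "AAKBBR", "BBRCC"))
  # repeated cleavage sites collapse to a set
  expect_setequal(theoretical_digest("KKK", digest_spec(0, 1, 10)), "K")
  # trypsin/P: cleavage happens even before proline
  expect_setequal(theoretical_digest("AKPR", digest_spec(0, 1, 10)),
                  c("AK", "PR"))
  expect_error(theoretical_digest("AAk1"), "non-amino-acid")
  expect_equal(theoretical_digest("", digest_spec()), character(0))
})

test_that("digestion agrees with brute-force enumeration on random proteins", {
  set.seed(101)
  aa <- c("A", "G", "S", "K", "R", "P", "L", "V")
  for (rep in 1:5) {
    seqn <- paste(sample(aa, 300, replace = TRUE), collapse = "")
    spec <- digest_spec(max_missed_cleavages = sample(0:2, 1),
                        min_length = 2, max_length = 25)
    expect_setequal(theoretical_digest(seqn, spec),
                    oracle_digest(seqn, spec$max_missed_cleavages, 2, 25))
  }
})

test_that("parsimony grouping resolves the canonical small cases", {
  g <- parsimony_group(list(p1 = "A", p2 = "B"))
  expect_equal(length(g), 2)
  expect_setequal(vapply(g, `[[`, character(1), "lead"), c("A", "B"))

  g2 <- parsimony_group(list(p1 = "A", p2 = c("A", "B"), p3 = "C"))
  expect_equal(length(g2), 2)
  leads <- vapply(g2, `[[`, character(1), "lead")
  expect_setequal(leads, c("A", "C"))
  members_a <- g2[[which(leads == "A")]]$members
  expect_setequal(members_a, c("A", "B"))
  expect_equal(oracle_min_cover(list(p1 = "A", p2 = c("A", "B"), p3 = "C")),
               2)
})

test_that("grouping output is invariant to input ordering", {
  set.seed(7)
  m <- random_parsimony_instance(8, 25)
  ref <- parsimony_group(m)
  for (i in 1:5) {
    shuf <- m[sample(length(m))]
    shuf <- lapply(shuf, sample)  # also shuffle accession order
    expect_identical(parsimony_group(shuf), ref)
  }
})

test_that("retained groups cover every input peptide exactly once", {
  set.seed(8)
  for (i in 1:20) {
    m <- random_parsimony_instance(sample(3:10, 1), sample(5:30, 1))
    g <- parsimony_group(m)
    assigned <- unlist(lapply(g, `[[`, "peptides"))
    expect_setequal(assigned, names(m))
    expect_equal(length(assigned), length(m))  # exactly one group each
    expect_true(all(vapply(g, `[[`, numeric(1),
                           "unique_peptide_count") >= 1))
  }
})

test_that("greedy group counts match the exhaustive minimum cover on small instances", {
  set.seed(9)
  excess <- integer(0)
  for (i in 1:60) {
    m <- random_parsimony_instance(sample(3:8, 1), sample(4:15, 1))
    greedy <- attr(parsimony_group(m), "greedy_cover_size")
    opt <- oracle_min_cover(m)
    expect_gte(greedy, opt)
    excess <- c(excess, greedy - opt)
  }
  expect_lt(mean(excess), 0.1)
})

test_that("group size histogram conserves the group count", {
  g <- parsimony_group(list(p1 = "A", p2 = "B", p3 = "C"))
  expect_equal(group_size_summary(g), c("1" = 3L))
  g2 <- parsimony_group(list(p1 = c("A", "B"), p2 = "A", p3 = "C"))
  h <- group_size_summary(g2)
  expect_equal(sum(h), length(g2))
  expect_equal(h, c("1" = 1L, "2" = 1L))
  expect_error(parsimony_group(list(p1 = character(0))), "at least one")
  expect_equal(parsimony_group(list()), list())
})
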