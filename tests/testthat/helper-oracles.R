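# Independent oracles used across test files. Each re-derives a quantity by a
# route different from the package implementation.

# hand-coded HC3 sandwich for a weighted linear fit (whitened-model form)
oracle_hc3 <- function(x, y, w) {
  X <- cbind(1, x) * sqrt(w)
  yy <- y * sqrt(w)
  bread <- solve(crossprod(X))
  beta <- bread %*% crossprod(X, yy)
  e <- yy - X %*% beta
  h <- rowSums((X %*% bread) * X)
  meat <- crossprod(X * as.numeric(e / (1 - h)))
  bread %*% meat %*% bread
}

# from-scratch one-way ANOVA sums of squares (unbalanced)
oracle_anova <- function(values, groups) {
  g <- split(values, groups)
  a <- length(g)
  n <- length(values)
  grand <- mean(values)
  ssw <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2,
                    numeric(1)))
  list(ms_within = ssw / (n - a), ms_between = ssb / (a - 1))
}

# brute-force tryptic digest: enumerate every substring and keep those whose
# boundaries are legal cleavage points with the allowed missed-cleavage count
oracle_digest <- function(sequence, max_missed, min_len, max_len) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cuts <- c(0, which(chars %in% c("K", "R") & seq_len(n) < n), n)
  cuts <- unique(cuts)
  out <- character(0)
  for (i in seq_along(cuts)) {
    for (j in seq_along(cuts)) {
      if (cuts[j] <= cuts[i]) next
      internal <- sum(cuts > cuts[i] & cuts < cuts[j])
      len <- cuts[j] - cuts[i]
      if (internal <= max_missed && len >= min_len && len <= max_len)
        out <- c(out, paste(chars[(cuts[i] + 1):cuts[j]], collapse = ""))
    }
  }
  sort(unique(out))
}

# exhaustive minimum set cover size over accession subsets
oracle_min_cover <- function(peptide_map) {
  accs <- sort(unique(unlist(peptide_map)))
  n_pep <- length(peptide_map)
  pep_sets <- lapply(accs, function(a)
    which(vapply(peptide_map, function(s) a %in% s, logical(1))))
  for (k in seq_along(accs)) {
    combos <- utils::combn(length(accs), k, simplify = FALSE)
    for (cmb in combos) {
      if (length(unique(unlist(pep_sets[cmb]))) == n_pep) return(k)
    }
  }
  length(accs)
}

# random peptide->accession instance for parsimony stress tests
random_parsimony_instance <- function(n_acc, n_pep) {
  accs <- paste0("A", seq_len(n_acc))
  m <- lapply(seq_len(n_pep), function(i)
    sample(accs, sample.int(min(3, n_acc), 1)))
  names(m) <- paste0("p", seq_len(n_pep))
  m
}

# orthogonal-regression slope via principal axis of the covariance matrix
# (independent closed-form route for Deming at lambda = 1)
oracle_deming_lambda1 <- function(x, y) {
  v <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
  slope <- v[2] / v[1]
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# CCC through the r * C_b factorization (alternate route)
oracle_ccc <- function(x, y) {
  n <- length(x)
  sx <- sqrt(stats::var(x) * (n - 1) / n)
  sy <- sqrt(stats::var(y) * (n - 1) / n)
  r <- stats::cor(x, y)
  v <- sx / sy
  u <- (mean(x) - mean(y)) / sqrt(sx * sy)
  cb <- 2 / (v + 1 / v + u^2)
  r * cb
}

# study-condition helpers shared by property tests
paper_design <- function() validation_design()
paper_truth <- function() synthetic_truth()

# true relative-error bias of the default truth at nominal amount mu
truth_bias <- function(truth, mu) {
  100 * ((truth$beta0 + truth$beta1 * mu) / mu - 1)
}

# scale factor mapping (u + e) percent noise to the RE-vs-nominal scale
truth_re_scale <- function(truth, mu) {
  (truth$beta0 + truth$beta1 * mu) / mu
}
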