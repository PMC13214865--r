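#' Build a shuffled entrapment peptide set
#'
#' For every unique target peptide the internal residues are permuted while
#' the C-terminal residue (the tryptic cleavage site) is kept fixed; a
#' shuffle colliding with the target peptidome (or an already generated
#' entrapment) is re-drawn up to `max_attempts` times and the peptide is
#' dropped if no collision-free permutation is found. Amino-acid composition
#' and the C-terminal residue are preserved for every emitted peptide.
#'
#' @param target_peptides character vector of unique target peptides.
#' @param seed integer seed.
#' @param max_attempts shuffle attempts per peptide before dropping it.
#' @return List with `entrapment` (character vector), `dropped` (peptides
#'   with no resolvable shuffle) and `r` (achieved entrapment/target ratio).
#' @export
build_shuffled_entrapment <- function(target_peptides, seed = 1L,
                                      max_attempts = 20L) {
  target_peptides <- unique(target_peptides)
  target_set <- new.env(hash = TRUE, parent = emptyenv())
  for (p in target_peptides) assign(p, TRUE, envir = target_set)
  with_seed(seed, {
    out <- character(0); dropped <- character(0)
    for (p in target_peptides) {
      n <- nchar(p)
      chars <- strsplit(p, "")[[1]]
      hit <- NA_character_
      if (n >= 2) {
        for (a in seq_len(max_attempts)) {
          perm <- c(sample(chars[-n]), chars[n])
          cand <- paste(perm, collapse = "")
          if (!exists(cand, envir = target_set, inherits = FALSE)) {
            hit <- cand
            assign(cand, TRUE, envir = target_set)  # keep entrapments unique
            break
          }
        }
      }
      if (is.na(hit)) dropped <- c(dropped, p) else out <- c(out, hit)
    }
    list(entrapment = out, dropped = dropped,
         r = length(out) / length(target_peptides))
  })
}

#' Trim a foreign entrapment space against the target peptidome
#'
#' Set difference: foreign peptides overlapping the target peptidome are
#' removed.
#'
#' @param foreign_peptides,target_peptides character vectors of stripped
#'   sequences.
#' @return The trimmed foreign set.
#' @export
trim_foreign_entrapment <- function(foreign_peptides, target_peptides) {
  setdiff(unique(foreign_peptides), unique(target_peptides))
}

#' Collapse PSM rows to unique peptides with minimum q-value
#'
#' @param psm data frame with `sequence`, `q_value` and `label`
#'   (`"target"`/`"entrapment"`); a sequence carrying both labels is an
#'   error.
#' @return Data frame with one row per unique sequence: `sequence`, `label`,
#'   `q_value` (minimum over the sequence's rows).
#' @export
collapse_to_peptides <- function(psm) {
  stopifnot(all(c("sequence", "q_value", "label") %in% names(psm)))
  labs <- tapply(psm$label, psm$sequence, function(l) length(unique(l)))
  if (any(labs > 1))
    stop("conflicting target/entrapment labels for sequence(s): ",
         paste(names(labs)[labs > 1], collapse = ", "))
  q <- tapply(psm$q_value, psm$sequence, min)
  lab <- tapply(psm$label, psm$sequence, `[`, 1)
  data.frame(sequence = names(q), label = as.character(lab),
             q_value = as.numeric(q), row.names = NULL)
}

#' Empirical false discovery proportion at a q-value threshold
#'
#' `FDP(tau) = N_E(tau) * (1 + 1/r) / N_D(tau)` where `N_E` counts unique
#' entrapment peptides at or below `tau`, `N_D` counts all unique peptides
#' (target + entrapment) at or below `tau`, and `r` is the
#' entrapment-to-target unique-peptide ratio of the search space. For
#' `r = 1` this reduces to `2 N_E / N_D`. Returns 0 when `N_D = 0`.
#'
#' @param peptides collapsed peptide table (`sequence`, `label`, `q_value`).
#' @param tau q-value threshold.
#' @param r entrapment-to-target ratio, > 0.
#' @return Estimated FDP (fraction).
#' @export
fdp_estimate <- function(peptides, tau, r = 1) {
  stopifnot(r > 0)
  acc <- peptides$q_value <= tau
  nd <- sum(acc)
  if (nd == 0) return(0)
  ne <- sum(acc & peptides$label == "entrapment")
  ne * (1 + 1 / r) / nd
}

#' Empirical FDP curve over a threshold grid
#'
#' @param peptides collapsed peptide table.
#' @param tau_grid increasing vector of q-value thresholds.
#' @param r entrapment-to-target ratio.
#' @return Data frame: `tau`, `n_e`, `n_d`, `fdp`. Counts are nondecreasing
#'   in `tau`.
#' @export
fdp_curve <- function(peptides, tau_grid, r = 1) {
  stopifnot(r > 0)
  is_e <- peptides$label == "entrapment"
  n_e <- vapply(tau_grid, function(t) sum(peptides$q_value <= t & is_e),
                numeric(1))
  n_d <- vapply(tau_grid, function(t) sum(peptides$q_value <= t), numeric(1))
  fdp <- ifelse(n_d > 0, n_e * (1 + 1 / r) / n_d, 0)
  data.frame(tau = tau_grid, n_e = n_e, n_d = n_d, fdp = fdp)
}

#' Pointwise bootstrap bands for the FDP curve
#'
#' Unique stripped sequences are resampled with replacement, the FDP curve is
#' recomputed per resample, and pointwise 2.5/97.5 percentile bands are
#' returned.
#'
#' @param peptides collapsed peptide table.
#' @param tau_grid thresholds.
#' @param r entrapment-to-target ratio.
#' @param B bootstrap resamples (>= 200).
#' @param seed integer seed.
#' @return Data frame: `tau`, `fdp` (point estimate), `lower`, `upper`.
#' @export
bootstrap_fdp_bands <- function(peptides, tau_grid, r = 1, B = 1000,
                                seed = 1L) {
  if (B < 200) stop("B must be >= 200")
  n <- nrow(peptides)
  point <- fdp_curve(peptides, tau_grid, r)
  is_e <- peptides$label == "entrapment"
  q <- peptides$q_value
  brk <- c(-Inf, tau_grid, Inf)
  bin <- cut(q, brk, labels = FALSE, right = TRUE)  # bin i <= tau_grid[i]
  nb <- length(tau_grid) + 1
  boot <- with_seed(seed, {
    res <- matrix(0, B, length(tau_grid))
    for (b in seq_len(B)) {
      i <- sample.int(n, n, replace = TRUE)
      te <- tabulate(bin[i][is_e[i]], nbins = nb)
      td <- tabulate(bin[i], nbins = nb)
      ne <- cumsum(te)[seq_along(tau_grid)]
      nd <- cumsum(td)[seq_along(tau_grid)]
      res[b, ] <- ifelse(nd > 0, ne * (1 + 1 / r) / nd, 0)
    }
    res
  })
  data.frame(tau = tau_grid, fdp = point$fdp,
             lower = apply(boot, 2, stats::quantile, 0.025),
             upper = apply(boot, 2, stats::quantile, 0.975))
}

#' Wilson score interval, optionally scaled
#'
#' Two-sided 95% Wilson score interval for a proportion, each bound
#' multiplied by `scale_factor` (used to scale the entrapment proportion by
#' `1 + 1/r`).
#'
#' @param successes,n counts with `0 <= successes <= n`, `n > 0`.
#' @param scale_factor multiplier applied to both bounds.
#' @param conf confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(successes, n, scale_factor = 1, conf = 0.95) {
  if (n == 0) stop("n must be > 0")
  stopifnot(successes >= 0, successes <= n)
  ci <- stats::prop.test(successes, n, conf.level = conf,
                         correct = FALSE)$conf.int
  as.numeric(ci) * scale_factor
}

#' Protein-level false discovery propagation
#'
#' Under approximate peptide independence, the probability that `k_required`
#' false-positive peptides map to the same protein group is
#' `peptide_fdp ^ k_required`; with the Hi3 requirement of three concordant
#' peptides and peptide FDP about 0.009 this is on the order of 1e-7.
#'
#' @param peptide_fdp peptide-level FDP in `[0, 1)`.
#' @param k_required concordant peptides required (>= 1).
#' @return Probability.
#' @export
protein_level_fdp <- function(peptide_fdp, k_required = 3L) {
  stopifnot(peptide_fdp >= 0, peptide_fdp < 1, k_required >= 1)
  peptide_fdp^k_required
}
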