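#' Ground-truth parameters for the synthetic-data generators
#'
#' Bundles the generator-side truth: the calibration line relating measured to
#' nominal total HCP, the two-level Gaussian error hierarchy on the
#' relative-error scale, the stratum-dependent calibration applied to
#' per-protein abundances, the log-normal abundance population, and the true
#' false discovery proportion for entrapment score tables.
#'
#' Defaults are the study conditions: calibration intercept 1.25 ng and slope
#' 0.798 (compressed recovery with a positive offset), within-assay SD 2.3 %
#' (the median repeatability), between-assay SD 1.0 % (a small positive
#' component, below the design's detectability floor of roughly
#' 1.41 x sigma_W), stratum slopes 1.0588/0.9906/0.9029/0.7986 with
#' intercepts 0.26/0.81/3.71/29.57 ppm from the lowest to the highest
#' abundance stratum, a log-normal abundance population with meanlog
#' `log(20)` and sdlog 1.5 ppm, and a true peptide-level FDP of 0.009.
#'
#' @param beta0 calibration intercept (ng).
#' @param beta1 calibration slope (dimensionless).
#' @param sigma_W within-assay (repeatability) SD, percent.
#' @param sigma_B between-assay SD, percent.
#' @param stratum_slopes,stratum_intercepts per-stratum calibration slope and
#'   intercept (ppm), lowest to highest abundance stratum.
#' @param abundance_log_mean,abundance_log_sd meanlog/sdlog of the log-normal
#'   per-protein anchor-level abundance population (ppm).
#' @param protein_noise_sd per-protein, per-observation multiplicative noise
#'   SD in percent for the abundance tables.
#' @param true_fdp true false discovery proportion at the operating q-value
#'   threshold for entrapment score generation.
#' @param seed default integer seed used by the generators.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(beta0 = 1.25, beta1 = 0.798,
                            sigma_W = 2.3, sigma_B = 1.0,
                            stratum_slopes = c(1.0588, 0.9906, 0.9029, 0.7986),
                            stratum_intercepts = c(0.26, 0.81, 3.71, 29.57),
                            abundance_log_mean = log(20),
                            abundance_log_sd = 1.5,
                            protein_noise_sd = 10,
                            true_fdp = 0.009,
                            seed = 1L) {
  stopifnot(sigma_W >= 0, sigma_B >= 0, true_fdp >= 0, true_fdp < 1,
            length(stratum_slopes) == length(stratum_intercepts))
  structure(list(beta0 = beta0, beta1 = beta1,
                 sigma_W = sigma_W, sigma_B = sigma_B,
                 stratum_slopes = stratum_slopes,
                 stratum_intercepts = stratum_intercepts,
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 protein_noise_sd = protein_noise_sd,
                 true_fdp = true_fdp, seed = as.integer(seed)),
            class = "synthetic_truth")
}

# run a generator under a local RNG state so generators are pure functions of
# (parameters, seed) and do not disturb the caller's RNG
with_seed <- function(seed, expr) {
  force(seed)  # must evaluate before snapshotting the RNG state
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate replicate-block reportable results with known truth
#'
#' For each assay `a` one between-assay effect `u_a ~ N(0, sigma_B^2)` is
#' drawn and shared across that assay's levels; for each replicate block an
#' independent within-assay error `e ~ N(0, sigma_W^2)` is drawn. The
#' reportable is `Y = (beta0 + beta1 * mu_j) * (1 + (u_a + e)/100)`: noise is
#' multiplicative on the ng scale, i.e. additive on the relative-error scale
#' on which all validation statistics operate.
#'
#' @param design a [validation_design()].
#' @param truth a [synthetic_truth()].
#' @param seed integer seed (defaults to `truth$seed`).
#' @return Data frame of replicate blocks: `assay`, `level`, `spike_ng`,
#'   `block`, `y_ng`, `re` (percent relative error vs nominal).
#' @export
gen_replicate_blocks <- function(design = validation_design(),
                                 truth = synthetic_truth(),
                                 seed = truth$seed) {
  layout <- design$layout
  spikes <- design$levels$spike_ng
  n_assay <- max(layout$assay)
  blocks <- merge(layout, data.frame(block = seq_len(design$preparations)))
  blocks <- blocks[order(blocks$assay, blocks$level, blocks$block), ]
  with_seed(seed, {
    u <- stats::rnorm(n_assay, 0, truth$sigma_B)
    e <- stats::rnorm(nrow(blocks), 0, truth$sigma_W)
    mu <- spikes[blocks$level]
    y <- (truth$beta0 + truth$beta1 * mu) * (1 + (u[blocks$assay] + e) / 100)
    data.frame(assay = blocks$assay, level = blocks$level, spike_ng = mu,
               block = blocks$block, y_ng = y,
               re = relative_error(y, mu), row.names = NULL)
  })
}

#' Generate a per-protein abundance table (ppm) with stratum-dependent truth
#'
#' Each protein draws a base anchor-level abundance from the log-normal
#' population and belongs to a truth-side abundance stratum (quantile bins of
#' the base abundance matching [assign_strata()]'s 5/25/50/75/100 cutpoints).
#' The theoretical abundance at level `j` scales the base abundance by the
#' spike ratio `S_j / S_anchor`; the observed abundance applies the stratum's
#' calibration line plus the hierarchical noise of [gen_replicate_blocks()]
#' and independent per-protein observation noise.
#'
#' @param truth a [synthetic_truth()].
#' @param n_proteins number of proteins (>= 120 so strata can clear the
#'   30-protein cell floor).
#' @param design a [validation_design()].
#' @param anchor_level level index used as the spike-ratio anchor (default 4).
#' @param seed integer seed.
#' @return Data frame with one row per (protein, assay, level, block):
#'   `protein`, `assay`, `level`, `block`, `spike_ng`, `ppm` (observed),
#'   `ppm_theo` (theoretical), `stratum_true`.
#' @export
gen_protein_ppm_table <- function(truth = synthetic_truth(),
                                  n_proteins = 1000,
                                  design = validation_design(),
                                  anchor_level = 4L,
                                  seed = truth$seed) {
  if (n_proteins < 120)
    stop("n_proteins must be >= 120 so strata can exceed the 30-protein floor")
  spikes <- design$levels$spike_ng
  layout <- design$layout
  n_assay <- max(layout$assay)
  n_strata <- length(truth$stratum_slopes)
  with_seed(seed, {
    base <- stats::rlnorm(n_proteins, truth$abundance_log_mean,
                          truth$abundance_log_sd)
    cuts <- stats::quantile(base, c(0.05, 0.25, 0.50, 0.75))
    stratum <- findInterval(base, cuts, left.open = FALSE)  # 0 = below P5
    cells <- merge(layout, data.frame(block = seq_len(design$preparations)))
    cells <- cells[order(cells$assay, cells$level, cells$block), ]
    u <- stats::rnorm(n_assay, 0, truth$sigma_B)
    e <- stats::rnorm(nrow(cells), 0, truth$sigma_W)
    out <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      lev <- cells$level[i]
      ratio <- spikes[lev] / spikes[anchor_level]
      theo <- base * ratio
      sl <- ifelse(stratum >= 1, truth$stratum_slopes[pmax(stratum, 1)], 1)
      ic <- ifelse(stratum >= 1, truth$stratum_intercepts[pmax(stratum, 1)], 0)
      eta <- stats::rnorm(n_proteins, 0, truth$protein_noise_sd)
      obs <- (ic + sl * theo) *
        (1 + (u[cells$assay[i]] + e[i] + eta) / 100)
      out[[i]] <- data.frame(protein = paste0("P", seq_len(n_proteins)),
                             assay = cells$assay[i], level = lev,
                             block = cells$block[i], spike_ng = spikes[lev],
                             ppm = obs, ppm_theo = theo,
                             stratum_true = ifelse(stratum == 0, NA_integer_,
                                                   pmin(stratum, n_strata)))
    }
    do.call(rbind, out)
  })
}

#' Generate a synthetic peptide observation table
#'
#' Builds peptide-level intensities for a set of synthetic proteins so the
#' whole filtering + Hi3 chain can be exercised against known truth. Each
#' protein contributes `n_peptides` peptides whose noiseless intensities sum
#' (over the top 3) to `fmol * rf`, so that the Hi3 pipeline returns each
#' protein's true mass exactly when noise, outliers and dropout are zero.
#'
#' @param proteins data frame with columns `accession`, `mw` (Da), `fmol`
#'   (amount per injection) and optionally `n_peptides` (default 5).
#' @param rf true response factor (intensity per fmol).
#' @param n_runs technical injections per peptide.
#' @param noise_cv multiplicative log-normal intensity noise CV in percent.
#' @param outlier_rate fraction of observations multiplied by 50.
#' @param dropout_rate fraction of observations removed at random.
#' @param seed integer seed.
#' @return Data frame of observations: `sequence`, `accession`, `run_id`,
#'   `intensity`, `q_value`, `is_heavy`, plus `is_outlier` flagging injected
#'   outliers (ground truth for filter tests).
#' @export
gen_peptide_table <- function(proteins, rf = 100, n_runs = 3,
                              noise_cv = 0, outlier_rate = 0,
                              dropout_rate = 0, seed = 1L) {
  stopifnot(all(c("accession", "mw", "fmol") %in% names(proteins)))
  n_pep <- if ("n_peptides" %in% names(proteins)) proteins$n_peptides
           else rep(5L, nrow(proteins))
  if (any(n_pep < 3)) stop("each synthetic protein needs >= 3 peptides")
  with_seed(seed, {
    rows <- vector("list", nrow(proteins))
    aa <- c("A", "D", "E", "F", "G", "H", "I", "L", "N", "Q", "S", "T",
            "V", "W", "Y")
    for (p in seq_len(nrow(proteins))) {
      k <- n_pep[p]
      seqs <- vapply(seq_len(k), function(i)
        paste0(paste(sample(aa, 8, replace = TRUE), collapse = ""),
               sample(c("K", "R"), 1)), character(1))
      # descending shares; top 3 shares sum to 1 so top-3 total = fmol * rf
      w <- 2^(-(seq_len(k) - 1))
      share <- w / sum(w[1:3])
      base <- proteins$fmol[p] * rf * share
      grid <- expand.grid(pep = seq_len(k), run = seq_len(n_runs))
      int <- base[grid$pep]
      if (noise_cv > 0)
        int <- int * exp(stats::rnorm(nrow(grid), 0, noise_cv / 100))
      is_out <- stats::runif(nrow(grid)) < outlier_rate
      int[is_out] <- int[is_out] * 50
      keep <- stats::runif(nrow(grid)) >= dropout_rate
      rows[[p]] <- data.frame(sequence = seqs[grid$pep],
                              accession = proteins$accession[p],
                              run_id = paste0("run", grid$run),
                              intensity = int,
                              q_value = 0.001, is_heavy = TRUE,
                              is_outlier = is_out)[keep, ]
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate target/entrapment q-value tables with known true FDP
#'
#' `n_target` true target peptides receive q-values concentrated below the
#' operating threshold `tau0`; false candidates receive uniform q-values and
#' are labelled entrapment with probability `r / (1 + r)` (the entrapment
#' share of the false sequence space). The number of false candidates is
#' chosen so that the expected false fraction among acceptances at `tau0`
#' equals `true_fdp`, making the scaled entrapment estimator unbiased there.
#'
#' @param n_target number of true target peptides.
#' @param r entrapment-to-target unique-peptide ratio of the search space.
#' @param true_fdp true false discovery proportion at `tau0`.
#' @param seed integer seed.
#' @param tau0 operating q-value threshold (default 0.01).
#' @return Data frame: `sequence`, `label` (`"target"`/`"entrapment"`),
#'   `q_value`, `is_false` (ground truth).
#' @export
gen_entrapment_scores <- function(n_target = 20000, r = 1,
                                  true_fdp = 0.009, seed = 1L,
                                  tau0 = 0.01) {
  stopifnot(r > 0, true_fdp >= 0, true_fdp < 1)
  with_seed(seed, {
    q_true <- tau0 * stats::runif(n_target)^2
    m <- if (true_fdp > 0)
      round(true_fdp * n_target / (tau0 * (1 - true_fdp))) else 0
    if (m > 0) {
      q_false <- stats::runif(m)
      lab <- ifelse(stats::runif(m) < r / (1 + r), "entrapment", "target")
    } else {
      q_false <- numeric(0)
      lab <- character(0)
    }
    data.frame(sequence = paste0("PEP", seq_len(n_target + m)),
               label = c(rep("target", n_target), lab),
               q_value = c(q_true, q_false),
               is_false = c(rep(FALSE, n_target), rep(TRUE, m)))
  })
}
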