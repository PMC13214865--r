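#' Peptide filter configuration
#'
#' Thresholds for the peptide-level filter chain applied before Hi3
#' quantification. Order of application is fixed: single-hit exclusion, total
#' ion current (TIC) normalization, intensity-deviation screening, modified
#' Z-score outlier removal, replicate CV filtering (normalization precedes all
#' outlier statistics).
#'
#' @param modified_z_cutoff modified Z-score cutoff (default 3.5).
#' @param cv_cutoff_percent replicate CV cutoff in percent (default 20).
#' @param intensity_deviation_factor maximum fold deviation from a peptide's
#'   cross-run median intensity (default 10).
#' @param single_hit_min_runs minimum technical injections a peptide must be
#'   observed in (default 2).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(modified_z_cutoff = 3.5, cv_cutoff_percent = 20,
                          intensity_deviation_factor = 10,
                          single_hit_min_runs = 2L) {
  stopifnot(modified_z_cutoff > 0, cv_cutoff_percent > 0,
            intensity_deviation_factor > 0, single_hit_min_runs > 0)
  structure(list(modified_z_cutoff = modified_z_cutoff,
                 cv_cutoff_percent = cv_cutoff_percent,
                 intensity_deviation_factor = intensity_deviation_factor,
                 single_hit_min_runs = as.integer(single_hit_min_runs)),
            class = "filter_config")
}

#' Total ion current normalization
#'
#' Scales each run's intensities so that every run's summed intensity equals
#' the median of the original run totals; within-run intensity ratios are
#' preserved.
#'
#' @param observations data frame with `run_id` and `intensity` columns.
#' @return The data frame with normalized intensities.
#' @export
tic_normalize <- function(observations) {
  totals <- tapply(observations$intensity, observations$run_id, sum)
  if (any(totals == 0))
    stop("run(s) with zero total intensity: ",
         paste(names(totals)[totals == 0], collapse = ", "))
  target <- stats::median(totals)
  observations$intensity <- as.numeric(observations$intensity *
    (target / totals[as.character(observations$run_id)]))
  observations
}

#' Modified Z-scores of a numeric vector
#'
#' `M_i = 0.6745 * (x_i - median) / MAD`. When the MAD is zero the mean
#' absolute deviation with the 0.7979 consistency scaling is used instead;
#' when that is also zero all scores are zero.
#'
#' @param values numeric vector.
#' @return Numeric vector of modified Z-scores.
#' @export
modified_zscore <- function(values) {
  m <- stats::median(values)
  mad0 <- stats::median(abs(values - m))
  if (mad0 > 0) return(0.6745 * (values - m) / mad0)
  meanad <- mean(abs(values - m))
  if (meanad > 0) return((values - m) / (1.253314 * meanad))
  rep(0, length(values))
}

#' Modified Z-score outlier filter
#'
#' Removes values whose absolute modified Z-score exceeds the cutoff. With
#' fewer than 3 values the series is passed through unchanged (flagged via
#' the `"filtered"` attribute).
#'
#' @param values numeric vector.
#' @param cutoff modified Z cutoff (default 3.5).
#' @return Kept values; attribute `"filtered"` is `FALSE` when the series was
#'   too short to filter.
#' @examples
#' modified_zscore_filter(c(1, 2, 3, 4, 100))
#' @export
modified_zscore_filter <- function(values, cutoff = 3.5) {
  if (length(values) < 3)
    return(structure(values, filtered = FALSE))
  keep <- abs(modified_zscore(values)) <= cutoff
  structure(values[keep], filtered = TRUE)
}

#' Replicate CV filter
#'
#' @param values replicate intensities for one peptide (>= 2 values).
#' @param cutoff CV cutoff in percent.
#' @return `TRUE` to keep the peptide (CV <= cutoff), `FALSE` to drop it. A
#'   zero mean drops the peptide.
#' @export
cv_filter <- function(values, cutoff = 20) {
  if (length(values) < 2) stop("cv_filter needs >= 2 replicate values")
  m <- mean(values)
  if (m == 0) return(FALSE)
  100 * stats::sd(values) / m <= cutoff
}

#' Response factor from spiked standards
#'
#' `RF = median_k(I_k / n_k)`, the median intensity per fmol over the
#' standards.
#'
#' @param intensity Hi3 intensities `I_k` of the standards.
#' @param fmol injected amounts `n_k` in fmol (> 0).
#' @return List of class `response_factor` with `rf` and the standards table.
#' @export
response_factor <- function(intensity, fmol) {
  if (length(intensity) == 0) stop("at least one standard is required")
  stopifnot(length(intensity) == length(fmol))
  if (any(fmol <= 0)) stop("standard amounts must be > 0 fmol")
  rf <- stats::median(intensity / fmol)
  structure(list(rf = rf,
                 standards = data.frame(intensity = intensity, fmol = fmol)),
            class = "response_factor")
}

# average (not monoisotopic) residue masses, Da
.aa_avg_mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
                  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
                  H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
                  M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
                  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_avg_mass <- 18.01528

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, the protein-level mass
#' convention used to convert fmol to ng.
#'
#' @param sequence amino-acid sequence over the 20 standard residues.
#' @return Molecular weight in Da.
#' @examples
#' compute_mw("G") # ~75.07
#' @export
compute_mw <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("empty sequence")
  chars <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(chars, names(.aa_avg_mass))
  if (length(unknown) > 0)
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  sum(.aa_avg_mass[chars]) + .water_avg_mass
}

#' Hi3 protein mass
#'
#' `mass_ng = (I_HCP / RF) * MW * 1e-6`, where `I_HCP` is the summed
#' intensity of the protein group's three highest mean-intensity peptides,
#' `I_HCP / RF` is the protein amount in fmol and `MW` is the lead protein's
#' molecular weight in Da. Groups with fewer than three quantifiable peptides
#' are not quantified.
#'
#' @param peptide_intensities named numeric vector of per-peptide mean
#'   intensities across the replicate block (>= 3 peptides); names are
#'   peptide sequences (lexicographic tie-break for the top-3 selection).
#' @param rf response factor (intensity per fmol), > 0.
#' @param mw molecular weight of the lead protein (Da), > 0.
#' @return Mass in ng.
#' @examples
#' hi3_protein_mass(c(a = 500, b = 300, c = 200), rf = 100, mw = 50000) # 0.5
#' @export
hi3_protein_mass <- function(peptide_intensities, rf, mw) {
  if (length(peptide_intensities) < 3)
    stop("Hi3 requires >= 3 quantifiable peptides")
  stopifnot(rf > 0, mw > 0)
  nm <- names(peptide_intensities)
  if (is.null(nm)) nm <- as.character(seq_along(peptide_intensities))
  ord <- order(-peptide_intensities, nm)
  i_hcp <- sum(peptide_intensities[ord[1:3]])
  (i_hcp / rf) * mw * 1e-6
}

#' Total HCP and ppm conversion
#'
#' Total HCP is the sum of all inferred protein-group masses; ppm is ng of
#' HCP per mg of product.
#'
#' @param masses_ng per-group masses in ng.
#' @param ng total HCP mass in ng.
#' @param mab_mg product mass per injection in mg, > 0.
#' @return `total_hcp`: total mass in ng; `to_ppm`: abundance in ppm.
#' @export
total_hcp <- function(masses_ng) sum(masses_ng)

#' @rdname total_hcp
#' @export
to_ppm <- function(ng, mab_mg) {
  if (any(mab_mg <= 0)) stop("mab_mg must be > 0")
  ng / mab_mg
}

#' Filter peptide observations and quantify protein groups by Hi3
#'
#' Applies the full filter chain (single-hit exclusion, TIC normalization,
#' intensity-deviation screening, modified Z-score outlier removal, replicate
#' CV filtering) to a peptide observation table, then computes Hi3 masses per
#' protein group. Groups left with fewer than three quantifiable peptides are
#' excluded with a reason code.
#'
#' @param observations data frame with `sequence`, `accession` (or a `groups`
#'   assignment), `run_id`, `intensity`.
#' @param rf response factor (number or [response_factor()] object).
#' @param mw_map named numeric vector: accession/group lead -> MW in Da.
#' @param config a [filter_config()].
#' @param mab_mg optional product mass (mg) for ppm reporting.
#' @return List with `proteins` (per-group table: `accession`, `i_hcp`,
#'   `fmol`, `mass_ng`, and `ppm` when `mab_mg` is given), `total_ng`,
#'   `excluded` (accession + reason), and `filtered` observation table.
#' @export
hi3_quantify <- function(observations, rf, mw_map,
                         config = filter_config(), mab_mg = NULL) {
  if (inherits(rf, "response_factor")) rf <- rf$rf
  obs <- observations

  # 1. single-hit exclusion: peptide must appear in >= min runs
  runs_per_pep <- tapply(obs$run_id, obs$sequence,
                         function(r) length(unique(r)))
  keep_pep <- names(runs_per_pep)[runs_per_pep >= config$single_hit_min_runs]
  obs <- obs[obs$sequence %in% keep_pep, , drop = FALSE]
  if (nrow(obs) == 0)
    return(list(proteins = data.frame(), total_ng = 0,
                excluded = data.frame(), filtered = obs))

  # 2. TIC normalization
  obs <- tic_normalize(obs)

  # 3. intensity-deviation screening vs cross-run median per peptide
  med <- tapply(obs$intensity, obs$sequence, stats::median)
  ratio <- obs$intensity / med[obs$sequence]
  obs <- obs[ratio <= config$intensity_deviation_factor &
               ratio >= 1 / config$intensity_deviation_factor, , drop = FALSE]

  # 4. modified Z-score outlier removal within peptide
  keep <- rep(TRUE, nrow(obs))
  for (s in unique(obs$sequence)) {
    i <- which(obs$sequence == s)
    if (length(i) >= 3)
      keep[i] <- abs(modified_zscore(obs$intensity[i])) <=
        config$modified_z_cutoff
  }
  obs <- obs[keep, , drop = FALSE]

  # 5. replicate CV filter per peptide
  drop_pep <- vapply(split(obs$intensity, obs$sequence), function(v)
    length(v) >= 2 && !cv_filter(v, config$cv_cutoff_percent), logical(1))
  obs <- obs[!obs$sequence %in% names(drop_pep)[drop_pep], , drop = FALSE]

  # Hi3 per protein group
  res <- list(); excl <- list()
  for (a in sort(unique(obs$accession))) {
    sub <- obs[obs$accession == a, , drop = FALSE]
    means <- tapply(sub$intensity, sub$sequence, mean)
    if (length(means) < 3) {
      excl[[a]] <- data.frame(accession = a,
                              reason = "fewer than 3 quantifiable peptides")
      next
    }
    if (!a %in% names(mw_map)) {
      excl[[a]] <- data.frame(accession = a, reason = "no molecular weight")
      next
    }
    mass <- hi3_protein_mass(stats::setNames(as.numeric(means),
                                             names(means)), rf, mw_map[[a]])
    ord <- order(-means, names(means))
    res[[a]] <- data.frame(accession = a,
                           i_hcp = sum(means[ord[1:3]]),
                           fmol = sum(means[ord[1:3]]) / rf,
                           mass_ng = mass)
  }
  proteins <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
              else data.frame(accession = character(), i_hcp = numeric(),
                              fmol = numeric(), mass_ng = numeric())
  if (!is.null(mab_mg) && nrow(proteins) > 0)
    proteins$ppm <- to_ppm(proteins$mass_ng, mab_mg)
  list(proteins = proteins,
       total_ng = total_hcp(proteins$mass_ng),
       excluded = if (length(excl)) do.call(rbind, c(excl,
                                                     make.row.names = FALSE))
                  else data.frame(accession = character(),
                                  reason = character()),
       filtered = obs)
}
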