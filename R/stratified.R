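#' Assign fixed abundance strata from anchor-level abundances
#'
#' Cutpoints at the 5th, 25th, 50th, 75th and 100th empirical percentiles
#' (linear interpolation) of the per-protein mean anchor-level abundance.
#' Proteins below the 5th percentile are excluded (they carry unstable
#' estimates); Q1 = [P5, P25), Q2 = [P25, P50), Q3 = [P50, P75),
#' Q4 = [P75, max]. Membership is deterministic and fixed once computed.
#'
#' @param abundance named numeric vector: protein -> mean anchor abundance
#'   (ppm); >= 120 proteins required so strata can clear the 30-protein cell
#'   floor.
#' @return Object of class `stratification`: `stratum` (named integer vector
#'   1-4 for retained proteins), `excluded_below_p5` (names), `cutpoints`.
#' @export
assign_strata <- function(abundance) {
  if (length(abundance) < 120)
    stop("need >= 120 proteins to form abundance strata")
  if (is.null(names(abundance))) stop("abundance must be a named vector")
  cuts <- stats::quantile(abundance, c(0.05, 0.25, 0.50, 0.75),
                          names = FALSE)
  if (any(duplicated(cuts)))
    stop("degenerate stratum cutpoints (tied percentiles); abundances need ",
         "jitter or the stratification is not applicable")
  excluded <- names(abundance)[abundance < cuts[1]]
  keep <- abundance[abundance >= cuts[1]]
  stratum <- findInterval(keep, cuts, left.open = FALSE)
  # order by value then name for deterministic membership under ties
  structure(list(stratum = stats::setNames(as.integer(stratum), names(keep)),
                 excluded_below_p5 = excluded,
                 cutpoints = stats::setNames(cuts,
                                             c("P5", "P25", "P50", "P75"))),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat("Abundance stratification: Q1-Q4 sizes",
      paste(tabulate(x$stratum, 4), collapse = "/"),
      "(", length(x$excluded_below_p5), "below P5 excluded )\n")
  cat("  cutpoints (ppm):",
      paste(sprintf("%s=%.3g", names(x$cutpoints), x$cutpoints),
            collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap reportable for one stratum cell
#'
#' Mean over `B` bootstrap resample means of the cell's per-protein ppm
#' values; in expectation equal to the cell mean, with negligible bootstrap
#' noise at large `B`.
#'
#' @param values per-protein ppm values in the cell (>= 30).
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param min_proteins exclusion floor.
#' @return The bootstrap-expected cell mean (ppm), or `NA` with attribute
#'   `"reason"` when the cell has fewer than `min_proteins` proteins.
#' @export
bootstrap_reportable <- function(values, B = 10000, seed = 1L,
                                 min_proteins = 30) {
  n <- length(values)
  if (n < min_proteins)
    return(structure(NA_real_, reason = "fewer than 30 proteins"))
  with_seed(seed, {
    idx <- sample.int(n, n * B, replace = TRUE)
    mean(colMeans(matrix(values[idx], n, B)))
  })
}

#' Stratum-cell reportables for a per-protein abundance table
#'
#' Applies [bootstrap_reportable()] to every (assay, level, block, stratum)
#' cell. Cells under the protein floor are excluded with a reason; counts are
#' conserved (retained + excluded = input cells).
#'
#' @param ppm_table data frame with `protein`, `assay`, `level`, `block`,
#'   `spike_ng`, `ppm`, and optionally `ppm_theo` (theoretical abundance,
#'   averaged per cell into `x_theo`).
#' @param strat a [assign_strata()] result.
#' @param B bootstrap resamples per cell.
#' @param seed integer seed.
#' @param min_proteins cell exclusion floor.
#' @return List: `cells` (retained cells with `mu_hat`, `n_proteins`,
#'   `x_theo`), `excluded` (cells with reasons).
#' @export
stratum_cells <- function(ppm_table, strat, B = 10000, seed = 1L,
                          min_proteins = 30) {
  tab <- ppm_table[ppm_table$protein %in% names(strat$stratum), ]
  tab$stratum <- strat$stratum[tab$protein]
  key <- interaction(tab$assay, tab$level, tab$block, tab$stratum,
                     drop = TRUE)
  pieces <- split(tab, key)
  rows <- vector("list", length(pieces)); excl <- list()
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    cell <- data.frame(assay = p$assay[1], level = p$level[1],
                       block = p$block[1], spike_ng = p$spike_ng[1],
                       stratum = p$stratum[1], n_proteins = nrow(p))
    if (nrow(p) < min_proteins) {
      cell$reason <- "fewer than 30 proteins"
      excl[[length(excl) + 1]] <- cell
      next
    }
    cell$mu_hat <- bootstrap_reportable(p$ppm, B = B,
                                        seed = seed + i,
                                        min_proteins = min_proteins)
    cell$x_theo <- if ("ppm_theo" %in% names(p)) mean(p$ppm_theo)
                   else NA_real_
    rows[[i]] <- cell
  }
  cells <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(cells) <- NULL
  list(cells = cells,
       excluded = if (length(excl)) do.call(rbind, excl)
                  else data.frame())
}

#' Stratum anchors and ratio-scale relative errors
#'
#' The stratum anchor is the mean reportable over all anchor-level cells of
#' the stratum; observed spike ratios are `mu_hat / anchor`, theoretical
#' ratios are `S_j / S_anchor`, and the ratio-scale relative error is
#' `100 * (R_obs - R_theo) / R_theo`. At the anchor level the stratum mean
#' relative error is zero by construction.
#'
#' @param cells retained cells from [stratum_cells()].
#' @param anchor_level anchor level index (default 4).
#' @return The cells with `anchor`, `r_obs`, `r_theo` and `re` columns.
#' @export
stratum_relative_errors <- function(cells, anchor_level = 4L) {
  anchors <- tapply(cells$mu_hat[cells$level == anchor_level],
                    cells$stratum[cells$level == anchor_level], mean)
  if (any(is.na(anchors)) || any(anchors == 0))
    stop("stratum anchor undefined or zero at the anchor level")
  s_anchor <- unique(cells$spike_ng[cells$level == anchor_level])
  cells$anchor <- as.numeric(anchors[as.character(cells$stratum)])
  cells$r_obs <- cells$mu_hat / cells$anchor
  cells$r_theo <- cells$spike_ng / s_anchor
  cells$re <- 100 * (cells$r_obs - cells$r_theo) / cells$r_theo
  cells
}

#' Per-stratum WLS calibration of reportables on theoretical abundance
#'
#' Regresses bootstrapped cell reportables on the cell-level theoretical
#' abundance per stratum, with per-level empirical-variance weights and HC3
#' sandwich inference (the same machinery as the aggregate calibration).
#'
#' @param cells retained cells with `mu_hat` and `x_theo`.
#' @param conf confidence level.
#' @return Data frame per stratum: slope, intercept, HC3 SEs and CIs,
#'   weighted R-squared.
#' @export
stratum_calibration <- function(cells, conf = 0.95) {
  stopifnot(all(is.finite(cells$x_theo)))
  rows <- lapply(sort(unique(cells$stratum)), function(b) {
    sub <- cells[cells$stratum == b, ]
    fit <- wls_calibration(data.frame(spike_ng = sub$x_theo,
                                      y_ng = sub$mu_hat),
                           pool_zero_variance = TRUE, conf = conf)
    data.frame(stratum = b, intercept = fit$beta0, slope = fit$beta1,
               intercept_se = fit$se_hc3[1], slope_se = fit$se_hc3[2],
               intercept_lo = fit$ci95_hc3[1, 1],
               intercept_hi = fit$ci95_hc3[1, 2],
               slope_lo = fit$ci95_hc3[2, 1], slope_hi = fit$ci95_hc3[2, 2],
               r_squared = fit$r_squared)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified total-error accuracy profiles
#'
#' Within each stratum, decomposes the ratio-scale relative errors per spike
#' level by one-way random-effects ANOVA with assay grouping, smooths the
#' total SD with the log-log model in the theoretical spike ratio, and
#' builds beta-expectation tolerance intervals with Welch-Satterthwaite df.
#' The validated domain is the intersection over strata of passing levels.
#'
#' @param cells cells augmented by [stratum_relative_errors()].
#' @param beta coverage probability.
#' @param limit symmetric acceptance limit (percent, default 35).
#' @return List: `table` (per stratum x level: bias, sigma_pred, nu_eff,
#'   interval, pass), `validated_levels` (level indices passing in every
#'   stratum), `domain` (range of passing theoretical ratios).
#' @export
stratum_accuracy_profile <- function(cells, beta = 0.95, limit = 35) {
  strata <- sort(unique(cells$stratum))
  rows <- list()
  for (b in strata) {
    sub <- cells[cells$stratum == b, ]
    levs <- sort(unique(sub$level))
    st <- lapply(levs, function(l) {
      s <- sub[sub$level == l, ]
      anova_mom(s$re, s$assay)
    })
    sigma_T <- vapply(st, `[[`, numeric(1), "sigma_T")
    n <- vapply(st, `[[`, numeric(1), "n")
    r_theo <- vapply(levs, function(l)
      sub$r_theo[sub$level == l][1], numeric(1))
    pos <- sigma_T > 0 & n > 1
    if (sum(pos) >= 2) {
      ab <- .loglog_wls(sigma_T[pos], r_theo[pos], n[pos] - 1)
      sigma_pred <- exp(ab[1] + ab[2] * log(r_theo))
    } else sigma_pred <- sigma_T
    for (i in seq_along(levs)) {
      nu <- satterthwaite_df(st[[i]]$sigma_W, st[[i]]$sigma_B,
                             max(st[[i]]$df_W, 1), st[[i]]$df_B,
                             st[[i]]$m_h)
      ti <- beta_expectation_ti(st[[i]]$bias, sigma_pred[i], nu, beta)
      rows[[length(rows) + 1]] <-
        data.frame(stratum = b, level = levs[i], r_theo = r_theo[i],
                   bias = st[[i]]$bias, sigma_T = sigma_T[i],
                   sigma_pred = sigma_pred[i], nu_eff = nu,
                   ti_lower = ti$lower, ti_upper = ti$upper,
                   pass = acceptance_decision(ti$lower, ti$upper, limit))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  pass_by_level <- tapply(tab$pass, tab$level, all)
  validated <- as.integer(names(pass_by_level)[pass_by_level])
  domain <- if (length(validated))
    range(tab$r_theo[tab$level %in% validated]) else c(NA_real_, NA_real_)
  list(table = tab, validated_levels = validated, domain = domain)
}

#' Abundance-aware LLOQ and ULOQ
#'
#' LLOQ: 95th percentile (conservative) and mean of the lowest-abundance
#' stratum's reportables at the lowest validated level. ULOQ: 5th percentile
#' (conservative) and mean of the highest-abundance stratum's reportables at
#' the highest validated level.
#'
#' @param cells cells with `mu_hat`.
#' @param validated_levels level indices passing in every stratum.
#' @param lloq_stratum,uloq_stratum stratum indices used for each limit.
#' @return List: `lloq` (`mean`, `p95`), `uloq` (`mean`, `p05`), with the
#'   levels used.
#' @export
abundance_lloq_uloq <- function(cells, validated_levels,
                                lloq_stratum = 1L, uloq_stratum = 4L) {
  if (length(validated_levels) == 0)
    stop("validated domain is empty; no abundance-aware limits")
  lo <- min(validated_levels); hi <- max(validated_levels)
  q1 <- cells$mu_hat[cells$stratum == lloq_stratum & cells$level == lo]
  q4 <- cells$mu_hat[cells$stratum == uloq_stratum & cells$level == hi]
  if (length(q1) == 0 || length(q4) == 0)
    stop("no cells available for the LLOQ/ULOQ strata at the boundary levels")
  list(lloq = list(mean = mean(q1),
                   p95 = unname(stats::quantile(q1, 0.95)), level = lo),
       uloq = list(mean = mean(q4),
                   p05 = unname(stats::quantile(q4, 0.05)), level = hi))
}

#' Abundance-stratified total-error analysis
#'
#' Convenience wrapper chaining stratification at the anchor level, cell
#' bootstrap reportables, ratio-scale relative errors, per-stratum
#' calibration, stratified accuracy profiles and abundance-aware limits.
#'
#' @param ppm_table per-protein abundance table (see [stratum_cells()]).
#' @param anchor_level anchor level index.
#' @param B cell bootstrap resamples.
#' @param seed integer seed.
#' @param beta coverage probability.
#' @param limit stratified acceptance limit (percent).
#' @return Object of class `stratified_te`: `stratification`, `cells`,
#'   `excluded`, `calibration` (when theoretical abundances are available),
#'   `profile`, `limits`.
#' @export
stratified_te <- function(ppm_table, anchor_level = 4L, B = 10000,
                          seed = 1L, beta = 0.95, limit = 35) {
  anchor <- ppm_table[ppm_table$level == anchor_level, ]
  ab <- tapply(anchor$ppm, anchor$protein, mean)
  strat <- assign_strata(stats::setNames(as.numeric(ab), names(ab)))
  sc <- stratum_cells(ppm_table, strat, B = B, seed = seed)
  cells <- stratum_relative_errors(sc$cells, anchor_level)
  calib <- if (all(is.finite(cells$x_theo))) stratum_calibration(cells)
           else NULL
  prof <- stratum_accuracy_profile(cells, beta = beta, limit = limit)
  lims <- if (length(prof$validated_levels))
    abundance_lloq_uloq(cells, prof$validated_levels) else NULL
  structure(list(stratification = strat, cells = cells,
                 excluded = sc$excluded, calibration = calib,
                 profile = prof, limits = lims),
            class = "stratified_te")
}

#' @export
print.stratified_te <- function(x, ...) {
  print(x$stratification)
  cat("Retained cells:", nrow(x$cells), "; excluded:",
      nrow(x$excluded), "\n")
  if (!is.null(x$calibration)) {
    cat("Per-stratum calibration slopes:",
        paste(sprintf("Q%d=%.3f", x$calibration$stratum,
                      x$calibration$slope), collapse = ", "), "\n")
  }
  v <- x$profile$validated_levels
  cat("Validated levels (all strata pass):",
      if (length(v)) paste(v, collapse = ", ") else "none", "\n")
  if (!is.null(x$limits))
    cat(sprintf("LLOQ: mean %.2f ppm (P95 %.2f); ULOQ: mean %.2f ppm (P05 %.2f)\n",
                x$limits$lloq$mean, x$limits$lloq$p95,
                x$limits$uloq$mean, x$limits$uloq$p05))
  invisible(x)
}
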