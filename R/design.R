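#' Construct a validation design
#'
#' Describes the hierarchical spike-recovery design used throughout the
#' package: the spike levels (nominal total HCP in ng per injection), which
#' levels each independent assay run includes, the number of independent
#' preparations (replicate blocks) per level and technical injections per
#' preparation, the tolerance-interval coverage probability, and the
#' acceptance limits on the relative-error scale.
#'
#' The default reproduces the seven-level, four-assay layout used for
#' validation: assay 1 carries the complete series L1--L7 (20--80 ng), assays
#' 2--4 carry L1, L2, L4, L6 and L7, and every included level is analysed as
#' three independent preparations in technical triplicate.
#'
#' @param spike_ng numeric vector of nominal spike amounts in ng, strictly
#'   increasing, one per level.
#' @param assay_levels list with one integer vector per assay giving the level
#'   indices included in that assay.
#' @param preparations independent preparations (replicate blocks) per level.
#' @param injections technical injections per preparation; their arithmetic
#'   mean is the reportable result.
#' @param beta coverage probability for beta-expectation tolerance intervals.
#' @param acceptance_limit_aggregate symmetric acceptance limit (percent) for
#'   the aggregate accuracy profile.
#' @param acceptance_limit_stratified symmetric acceptance limit (percent) for
#'   abundance-stratified profiles.
#' @param mab_mg product (mAb) mass per injection in mg, used to convert ng of
#'   HCP to ppm (ng HCP per mg product).
#' @return An object of class `validation_design`.
#' @examples
#' d <- validation_design()
#' d$levels
#' @export
validation_design <- function(spike_ng = c(20, 30, 40, 50, 60, 70, 80),
                              assay_levels = list(1:7, c(1L, 2L, 4L, 6L, 7L),
                                                  c(1L, 2L, 4L, 6L, 7L),
                                                  c(1L, 2L, 4L, 6L, 7L)),
                              preparations = 3L,
                              injections = 3L,
                              beta = 0.95,
                              acceptance_limit_aggregate = 30,
                              acceptance_limit_stratified = 35,
                              mab_mg = 0.5) {
  stopifnot(is.numeric(spike_ng), length(spike_ng) >= 1)
  if (any(spike_ng <= 0)) stop("spike amounts must be > 0")
  if (is.unsorted(spike_ng, strictly = TRUE))
    stop("spike amounts must be strictly increasing by level index")
  if (preparations < 1 || injections < 1)
    stop("preparations and injections must be >= 1")
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  if (acceptance_limit_aggregate <= 0 || acceptance_limit_stratified <= 0)
    stop("acceptance limits must be > 0")
  if (mab_mg <= 0) stop("mab_mg must be > 0")
  assay_levels <- lapply(assay_levels, as.integer)
  bad <- vapply(assay_levels,
                function(x) any(x < 1 | x > length(spike_ng)), logical(1))
  if (any(bad)) stop("assay_levels refers to an undefined level index")

  levels <- data.frame(level = seq_along(spike_ng),
                       label = paste0("L", seq_along(spike_ng)),
                       spike_ng = spike_ng)
  layout <- do.call(rbind, lapply(seq_along(assay_levels), function(a)
    data.frame(assay = a, level = assay_levels[[a]])))
  structure(list(levels = levels,
                 layout = layout,
                 preparations = as.integer(preparations),
                 injections = as.integer(injections),
                 beta = beta,
                 acceptance_limit_aggregate = acceptance_limit_aggregate,
                 acceptance_limit_stratified = acceptance_limit_stratified,
                 mab_mg = mab_mg),
            class = "validation_design")
}

#' @export
print.validation_design <- function(x, ...) {
  cat("Validation design:", nrow(x$levels), "spike levels,",
      length(unique(x$layout$assay)), "assays\n")
  cat("  levels (ng):", paste(x$levels$spike_ng, collapse = ", "), "\n")
  cat("  replicate blocks per level:", x$preparations,
      "preparations x", x$injections, "injections\n")
  cat("  beta =", x$beta, "; acceptance limits: +/-",
      x$acceptance_limit_aggregate, "% (aggregate), +/-",
      x$acceptance_limit_stratified, "% (stratified)\n")
  invisible(x)
}

#' Reportable result from technical injections
#'
#' The reportable result for one replicate block is the arithmetic mean of its
#' technical injections.
#'
#' @param values numeric vector of injection-level results (ng), all >= 0.
#' @return The arithmetic mean (ng).
#' @examples
#' reportable_from_injections(c(16, 17, 18))
#' @export
reportable_from_injections <- function(values) {
  if (length(values) == 0) stop("at least one injection value is required")
  if (any(!is.finite(values)) || any(values < 0))
    stop("injection values must be finite and >= 0")
  mean(values)
}

#' Relative error of a reportable result
#'
#' `RE = 100 * (Y - mu) / mu`, the replicate-block relative error in percent.
#' The inverse identity `Y = mu * (1 + RE/100)` holds to machine precision.
#'
#' @param y reportable result (ng).
#' @param mu nominal spike amount (ng), > 0.
#' @return Relative error in percent.
#' @examples
#' relative_error(64.79, 80) # -19.01
#' @export
relative_error <- function(y, mu) {
  if (any(mu <= 0)) stop("nominal spike amount must be > 0")
  100 * (y - mu) / mu
}
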