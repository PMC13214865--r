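#' Bracketed system-suitability disposition
#'
#' An analytical sequence is bracketed by spike recoveries at the
#' LLOQ-proximal level: the opening bracket gates sequence initiation and
#' the closing bracket gates release. Recoveries within the closed interval
#' `[lower, upper]` (default 70-130% of nominal) pass.
#'
#' @param opening,closing bracket recoveries in percent; `closing` may be
#'   `NA` when the sequence never started.
#' @param lower,upper specification bounds (percent), inclusive.
#' @return `"do not start"`, `"deviation investigation"` or `"release"`.
#' @export
bracket_decision <- function(opening, closing = NA, lower = 70,
                             upper = 130) {
  stopifnot(opening >= 0)
  if (opening < lower || opening > upper) return("do not start")
  if (is.na(closing)) stop("closing bracket recovery required once started")
  if (closing < lower || closing > upper) return("deviation investigation")
  "release"
}

#' Phase I individuals-moving-range control chart
#'
#' Individuals limits `center +/- 2.66 * mr_bar` (3-sigma with d2 = 1.128
#' for moving ranges of 2) and moving-range upper limit `3.267 * mr_bar`.
#' Violations flag individuals outside their limits and moving ranges above
#' their limit; specification-limit exceedances are flagged separately. With
#' fewer than 10 observations the control limits are withheld and only the
#' specification check runs.
#'
#' @param series run-level metric values in time order.
#' @param spec_limits optional `c(lower, upper)` specification limits.
#' @return Object of class `imr_chart`: `center`, `mr_bar`, `lcl`, `ucl`,
#'   `mr_ucl`, `violations` (indices), `mr_violations`, `spec_violations`,
#'   `limits_derived`.
#' @export
imr_chart <- function(series, spec_limits = NULL) {
  n <- length(series)
  mr <- abs(diff(series))
  out <- list(series = series, center = mean(series),
              mr_bar = if (n >= 2) mean(mr) else NA_real_,
              spec_limits = spec_limits)
  if (n >= 10) {
    out$lcl <- out$center - 2.66 * out$mr_bar
    out$ucl <- out$center + 2.66 * out$mr_bar
    out$mr_ucl <- 3.267 * out$mr_bar
    out$violations <- which(series < out$lcl | series > out$ucl)
    out$mr_violations <- which(mr > out$mr_ucl) + 1L
    out$limits_derived <- TRUE
  } else {
    out$lcl <- out$ucl <- out$mr_ucl <- NA_real_
    out$violations <- integer(0)
    out$mr_violations <- integer(0)
    out$limits_derived <- FALSE
  }
  out$spec_violations <- if (!is.null(spec_limits))
    which(series < spec_limits[1] | series > spec_limits[2]) else integer(0)
  structure(out, class = "imr_chart")
}

#' @export
print.imr_chart <- function(x, digits = 4, ...) {
  cat("I-MR chart:", length(x$series), "points, center",
      format(x$center, digits = digits), "\n")
  if (x$limits_derived) {
    cat("  individuals limits [",
        paste(format(c(x$lcl, x$ucl), digits = digits), collapse = ", "),
        "], MR UCL", format(x$mr_ucl, digits = digits), "\n")
    cat("  violations:", length(x$violations), "individuals,",
        length(x$mr_violations), "moving-range\n")
  } else cat("  < 10 points: control limits withheld (spec check only)\n")
  if (!is.null(x$spec_limits))
    cat("  specification exceedances:", length(x$spec_violations), "\n")
  invisible(x)
}

#' Retention-time-calibrant monitoring metrics
#'
#' From a matched peptide panel: the median retention-time deviation versus
#' a locked deployment reference (minutes) and the median MS1 intensity
#' deviation versus the Phase I baseline median (percent).
#'
#' @param observed_rt,reference_rt named numeric vectors over the same
#'   peptide panel (names are peptide identifiers).
#' @param ms1_intensity named numeric vector of observed MS1 intensities.
#' @param baseline_median Phase I baseline median MS1 intensity.
#' @return List: `delta_rt_median` (min), `ms1_deviation_percent`.
#' @export
rtc_metrics <- function(observed_rt, reference_rt, ms1_intensity,
                        baseline_median) {
  missing <- setdiff(names(reference_rt), names(observed_rt))
  if (length(missing) > 0)
    stop("peptide panel mismatch; missing: ",
         paste(missing, collapse = ", "))
  obs <- observed_rt[names(reference_rt)]
  list(delta_rt_median = stats::median(obs - reference_rt),
       ms1_deviation_percent =
         100 * (stats::median(ms1_intensity) / baseline_median - 1))
}
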