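#' Deming regression with paired-bootstrap confidence intervals
#'
#' Errors-in-variables regression of `y` on `x` with error-variance ratio
#' `lambda = var(e_y) / var(e_x)` (default 1: both axes measure the same
#' quantity on comparable systems). The closed-form estimate is
#' `slope = (syy - lambda*sxx + sqrt((syy - lambda*sxx)^2 + 4*lambda*sxy^2))
#' / (2*sxy)`; confidence intervals come from percentile bootstrap over
#' pairs.
#'
#' @param x,y paired measurements (n >= 3).
#' @param lambda_ratio error-variance ratio, > 0.
#' @param n_boot bootstrap resamples (default 2000); 0 skips the intervals.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return List of class `deming_fit`: `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`.
#' @export
deming_fit <- function(x, y, lambda_ratio = 1, n_boot = 2000, seed = 1L,
                       conf = 0.95) {
  stopifnot(length(x) == length(y), lambda_ratio > 0)
  n <- length(x)
  if (n < 3) stop("need >= 3 paired values")
  est <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y)
    sxy <- stats::cov(x, y)
    if (sxx == 0 && syy == 0) stop("zero variance in both series")
    if (sxy == 0) return(c(slope = NA_real_, intercept = NA_real_))
    lam <- lambda_ratio
    slope <- (syy - lam * sxx +
                sqrt((syy - lam * sxx)^2 + 4 * lam * sxy^2)) / (2 * sxy)
    c(slope = slope, intercept = mean(y) - slope * mean(x))
  }
  point <- est(x, y)
  ci <- NULL
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        tryCatch(est(x[i], y[i]), error = function(e)
          c(slope = NA_real_, intercept = NA_real_))
      }, c(slope = 0, intercept = 0)))
    })
    probs <- c((1 - conf) / 2, (1 + conf) / 2)
    ci <- apply(boot, 2, stats::quantile, probs, na.rm = TRUE)
  }
  structure(list(slope = unname(point["slope"]),
                 intercept = unname(point["intercept"]),
                 slope_ci = if (is.null(ci)) NULL else unname(ci[, "slope"]),
                 intercept_ci = if (is.null(ci)) NULL
                                else unname(ci[, "intercept"]),
                 lambda_ratio = lambda_ratio, n = n),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, digits = 4, ...) {
  cat("Deming regression (lambda =", x$lambda_ratio, "): slope",
      format(x$slope, digits = digits), ", intercept",
      format(x$intercept, digits = digits), "\n")
  if (!is.null(x$slope_ci))
    cat("  bootstrap 95% CI: slope [",
        paste(format(x$slope_ci, digits = digits), collapse = ", "),
        "], intercept [",
        paste(format(x$intercept_ci, digits = digits), collapse = ", "),
        "]\n")
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments. Identical constant series return 1 by
#' convention; unequal constant series return 0 (zero covariance against a
#' positive location penalty).
#'
#' @param x,y paired measurements (n >= 2).
#' @return CCC in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need >= 2 paired values")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) {
    if (all(x == y)) return(1)
    stop("zero denominator: constant unequal series")
  }
  2 * cxy / denom
}

#' Bland-Altman analysis on the relative-difference scale
#'
#' Relative differences `d_i = 100 * (y_i - x_i) / ((x_i + y_i) / 2)`
#' (pairwise-mean denominator); bias is the mean difference and the limits
#' of agreement are `bias +/- 1.96 * SD(d)` (sample SD).
#'
#' @param x,y paired measurements (n >= 3, all pairwise means > 0).
#' @return List of class `bland_altman`: `bias`, `loa` (lower, upper), `d`.
#' @export
bland_altman_relative <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need >= 3 paired values")
  m <- (x + y) / 2
  if (any(m <= 0)) stop("pairwise mean(s) <= 0; relative difference undefined")
  d <- 100 * (y - x) / m
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s),
                 d = d), class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat("Bland-Altman (relative scale): bias",
      format(x$bias, digits = digits), "%, LoA [",
      paste(format(x$loa, digits = digits), collapse = ", "), "] %\n")
  invisible(x)
}

#' Containment check of limits of agreement against an acceptance limit
#'
#' Pass iff both limits of agreement lie within the closed interval
#' `[-limit, +limit]`.
#'
#' @param stats a `bland_altman` object or numeric `c(lower, upper)`.
#' @param limit symmetric limit (percent).
#' @return Logical pass flag.
#' @export
containment_check <- function(stats, limit = 30) {
  loa <- if (inherits(stats, "bland_altman")) stats$loa else stats
  loa[1] >= -limit && loa[2] <= limit
}

#' Cross-software / cross-platform agreement summary
#'
#' Convenience wrapper combining Deming regression, Lin's CCC and
#' Bland-Altman limits of agreement with the containment decision.
#'
#' @param x,y paired total-HCP values (ng).
#' @param limit acceptance limit (percent).
#' @param n_boot,seed bootstrap controls for the Deming intervals.
#' @return List of class `agreement_stats`.
#' @export
agreement_stats <- function(x, y, limit = 30, n_boot = 2000, seed = 1L) {
  dem <- deming_fit(x, y, n_boot = n_boot, seed = seed)
  ba <- bland_altman_relative(x, y)
  structure(list(deming = dem, ccc = lin_ccc(x, y), bland_altman = ba,
                 within_limit = containment_check(ba, limit),
                 limit = limit),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, digits = 4, ...) {
  print(x$deming)
  cat("Lin's CCC:", format(x$ccc, digits = digits), "\n")
  print(x$bland_altman)
  cat("Within +/-", x$limit, "%:", if (x$within_limit) "yes" else "no", "\n")
  invisible(x)
}
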