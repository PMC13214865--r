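#' Weighted least-squares calibration of measured vs nominal total HCP
#'
#' Fits `Y = beta0 + beta1 * mu + e` to replicate-block reportable results
#' pooled across assays, with per-level weights equal to the reciprocal of
#' the empirical variance of reportables at that level (denominator n - 1).
#' Coefficient uncertainty uses HC3 heteroscedasticity-consistent sandwich
#' standard errors; Wald tests of `beta0 = 0` and `beta1 = 1` are reported.
#' The reported R-squared is the weighted R-squared of the WLS fit.
#'
#' @param blocks data frame of replicate blocks with columns `spike_ng` and
#'   `y_ng` (and anything else, ignored).
#' @param pool_zero_variance if `TRUE`, a level with zero empirical variance
#'   borrows the smallest positive level variance instead of erroring.
#' @param conf confidence level for the HC3 intervals.
#' @return Object of class `hcp_calibration`: coefficients, HC3 SEs and CIs,
#'   weighted R-squared, weights, residuals, p-values for `beta0 = 0` and
#'   `beta1 = 1`, and the underlying `lm` fit.
#' @export
wls_calibration <- function(blocks, pool_zero_variance = FALSE,
                            conf = 0.95) {
  stopifnot(all(c("spike_ng", "y_ng") %in% names(blocks)))
  mu <- blocks$spike_ng
  y <- blocks$y_ng
  levs <- sort(unique(mu))
  if (length(levs) < 2) stop("need >= 2 distinct spike levels")
  v <- vapply(levs, function(l) {
    yy <- y[mu == l]
    if (length(yy) < 2)
      stop("need >= 2 replicate blocks at each level for weights (level ",
           l, " ng)")
    stats::var(yy)
  }, numeric(1))
  if (any(v == 0)) {
    if (!pool_zero_variance)
      stop("zero empirical variance at level(s) ",
           paste(levs[v == 0], collapse = ", "),
           " ng; set pool_zero_variance = TRUE to borrow the minimum ",
           "positive level variance")
    if (all(v == 0)) stop("all level variances are zero; weights undefined")
    v[v == 0] <- min(v[v > 0])
  }
  w <- (1 / v)[match(mu, levs)]
  fit <- stats::lm(y ~ mu, weights = w)
  beta <- stats::coef(fit)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  se <- sqrt(diag(vc))
  df <- fit$df.residual
  tcrit <- stats::qt((1 + conf) / 2, df)
  ci <- cbind(beta - tcrit * se, beta + tcrit * se)
  p0 <- 2 * stats::pt(abs(beta[1] / se[1]), df, lower.tail = FALSE)
  p1 <- 2 * stats::pt(abs((beta[2] - 1) / se[2]), df, lower.tail = FALSE)
  # weighted R^2 of the WLS fit
  yw <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - yw)^2)
  structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                 se_hc3 = stats::setNames(se, c("beta0", "beta1")),
                 ci95_hc3 = matrix(ci, 2,
                                   dimnames = list(c("beta0", "beta1"),
                                                   c("lower", "upper"))),
                 r_squared = r2,
                 weights = stats::setNames(1 / v, levs),
                 residuals = stats::residuals(fit),
                 p_beta0_eq_0 = unname(p0), p_beta1_eq_1 = unname(p1),
                 df_residual = df, fit = fit),
            class = "hcp_calibration")
}

#' @export
print.hcp_calibration <- function(x, digits = 4, ...) {
  cat("WLS calibration: y =", format(x$beta0, digits = digits), "+",
      format(x$beta1, digits = digits), "x\n")
  cat("  HC3 SE: intercept", format(x$se_hc3[1], digits = digits),
      ", slope", format(x$se_hc3[2], digits = digits), "\n")
  cat("  95% CI (HC3): intercept [",
      paste(format(x$ci95_hc3[1, ], digits = digits), collapse = ", "),
      "], slope [",
      paste(format(x$ci95_hc3[2, ], digits = digits), collapse = ", "), "]\n")
  cat("  weighted R^2 =", format(x$r_squared, digits = digits),
      "; p(beta0=0) =", format(x$p_beta0_eq_0, digits = 3),
      "; p(beta1=1) =", format(x$p_beta1_eq_1, digits = 3), "\n")
  invisible(x)
}

#' @export
coef.hcp_calibration <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' @export
predict.hcp_calibration <- function(object, newdata, ...) {
  mu <- if (is.data.frame(newdata)) newdata$spike_ng else newdata
  object$beta0 + object$beta1 * mu
}

#' Model-implied relative bias of the calibration line
#'
#' `100 * (beta0 / x + beta1 - 1)` percent: the relative bias implied by the
#' fitted calibration at nominal amount `x`, approaching
#' `100 * (beta1 - 1)` as `x` grows.
#'
#' @param object an `hcp_calibration` fit, or the intercept `beta0` when
#'   `beta1` is supplied.
#' @param x nominal amount(s), > 0; `Inf` gives the asymptote.
#' @param beta1 slope, when `object` is the numeric intercept.
#' @return Implied relative bias in percent.
#' @examples
#' implied_relative_bias(1.25, 80, beta1 = 0.798) # -18.6
#' @export
implied_relative_bias <- function(object, x, beta1 = NULL) {
  if (inherits(object, "hcp_calibration")) {
    b0 <- object$beta0; b1 <- object$beta1
  } else {
    if (is.null(beta1)) stop("supply beta1 with a numeric intercept")
    b0 <- object; b1 <- beta1
  }
  if (any(x <= 0)) stop("x must be > 0")
  100 * (b0 / x + b1 - 1)
}
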