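#' Fit a total-error accuracy profile
#'
#' The central fitting function of the package. From a table of
#' replicate-block reportable results it computes, per spike level: the bias
#' (mean relative error), the method-of-moments variance decomposition with
#' assay as the random grouping factor, the log-log smoothed total SD, the
#' Welch-Satterthwaite effective degrees of freedom, the 95% beta-expectation
#' tolerance interval, optionally the 95/95 content tolerance interval by
#' hierarchical cluster bootstrap, and the acceptance decision against the
#' symmetric limit. The validated range and LLOQ follow from the per-level
#' decisions.
#'
#' @param blocks data frame of replicate blocks with columns `assay`,
#'   `spike_ng`, `y_ng` (or `re` directly).
#' @param design a [validation_design()] supplying `beta` and the acceptance
#'   limit (overridable via `beta` and `limit`).
#' @param beta coverage probability for the beta-expectation intervals.
#' @param limit symmetric acceptance limit in percent.
#' @param content_ti also compute 95/95 content intervals (requires >= 2
#'   assays).
#' @param B,M outer iterations and inner simulated errors for the content
#'   interval bootstrap.
#' @param seed integer seed for the content interval bootstrap.
#' @return An object of class `te_profile` with components `table` (one row
#'   per level), `level_stats`, `variance_model`, `blocks`, `range` (validated
#'   range + LLOQ), `beta`, `limit`.
#' @examples
#' blocks <- gen_replicate_blocks(seed = 7)
#' fit <- te_profile(blocks, content_ti = FALSE)
#' fit
#' @export
te_profile <- function(blocks, design = validation_design(),
                       beta = design$beta,
                       limit = design$acceptance_limit_aggregate,
                       content_ti = TRUE, B = 4000, M = 1000, seed = 1L) {
  if (!"re" %in% names(blocks)) blocks <- relative_errors(blocks)
  ls <- level_stats(blocks)
  vm <- fit_variance_model(ls$sigma_T, ls$spike_ng, ls$n)
  sigma_pred <- predict(vm, ls$spike_ng)
  nu <- mapply(satterthwaite_df, ls$sigma_W, ls$sigma_B, ls$df_W, ls$df_B,
               ls$m_h)
  k <- vapply(nu, coverage_factor, numeric(1), beta = beta)
  lower <- ls$bias - k * sigma_pred
  upper <- ls$bias + k * sigma_pred
  pass <- acceptance_decision(lower, upper, limit)
  tab <- data.frame(spike_ng = ls$spike_ng, mean_ng = ls$mean_ng,
                    bias = ls$bias, sigma_pred = sigma_pred, nu_eff = nu,
                    k = k, ti_lower = lower, ti_upper = upper, pass = pass)
  if (content_ti) {
    ct <- content_ti_95_95(blocks, B = B, M = M, seed = seed)
    i <- match(tab$spike_ng, ct$spike_ng)
    tab$content_lower <- ct$lower[i]
    tab$content_upper <- ct$upper[i]
    tab$content_pass <- acceptance_decision(tab$content_lower,
                                            tab$content_upper, limit)
  }
  rng <- validated_range(pass, tab$spike_ng)
  structure(list(table = tab, level_stats = ls, variance_model = vm,
                 blocks = blocks, range = rng, beta = beta, limit = limit),
            class = "te_profile")
}

#' @export
print.te_profile <- function(x, digits = 4, ...) {
  cat("Total-error accuracy profile (beta =", x$beta, ", limit +/-",
      x$limit, "%)\n\n")
  tab <- x$table
  out <- data.frame(spike_ng = tab$spike_ng,
                    bias = round(tab$bias, 2),
                    pred_sd = round(tab$sigma_pred, 2),
                    df = round(tab$nu_eff, 2),
                    ti = sprintf("[%.2f, %.2f]", tab$ti_lower, tab$ti_upper),
                    pass = ifelse(tab$pass, "yes", "no"))
  if ("content_lower" %in% names(tab))
    out$content_ti <- sprintf("[%.2f, %.2f]", tab$content_lower,
                              tab$content_upper)
  print(out, row.names = FALSE)
  if (is.na(x$range$lloq)) {
    cat("\nNo validated range",
        if (x$range$fragmented) "(fragmented passing set)" else "", "\n")
  } else {
    cat(sprintf("\nValidated range: %g-%g ng; LLOQ = %g ng\n",
                x$range$lower, x$range$upper, x$range$lloq))
  }
  invisible(x)
}

#' @export
summary.te_profile <- function(object, ...) {
  structure(list(profile = object), class = "summary.te_profile")
}

#' @export
print.summary.te_profile <- function(x, ...) {
  p <- x$profile
  print(p)
  cat("\nVariance components by level:\n")
  ls <- p$level_stats
  print(data.frame(spike_ng = ls$spike_ng,
                   sigma_W = round(ls$sigma_W, 2),
                   sigma_B = round(ls$sigma_B, 2),
                   sigma_T = round(ls$sigma_T, 2),
                   df_W = ls$df_W, df_B = ls$df_B,
                   truncated = ls$truncated), row.names = FALSE)
  cat("\nVariance model: ")
  print(p$variance_model)
  invisible(x)
}

#' Predict the tolerance interval at new spike amounts
#'
#' Uses the fitted variance model for the predicted SD and, conservatively,
#' the smallest effective df among the fitted levels for the coverage factor.
#'
#' @param object a `te_profile`.
#' @param newdata nominal amounts (ng) or data frame with `spike_ng`.
#' @param ... unused.
#' @return Data frame: `spike_ng`, `sigma_pred`, `k`, `half_width`.
#' @export
predict.te_profile <- function(object, newdata, ...) {
  mu <- if (is.data.frame(newdata)) newdata$spike_ng else newdata
  sp <- predict(object$variance_model, mu)
  k <- coverage_factor(min(object$table$nu_eff), object$beta)
  data.frame(spike_ng = mu, sigma_pred = sp, k = k, half_width = k * sp)
}

#' Plot an accuracy profile
#'
#' Bias with beta-expectation (and, when present, 95/95 content) tolerance
#' bounds against spike level, with the acceptance limits as horizontal
#' reference lines.
#'
#' @param x a `te_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.te_profile <- function(x, ...) {
  tab <- x$table
  ylim <- range(c(tab$ti_lower, tab$ti_upper, x$limit, -x$limit,
                  tab$content_lower, tab$content_upper), na.rm = TRUE)
  graphics::plot(tab$spike_ng, tab$bias, type = "b", pch = 16,
                 ylim = ylim, xlab = "Nominal spike (ng)",
                 ylab = "Relative error (%)",
                 main = "Total-error accuracy profile", ...)
  graphics::lines(tab$spike_ng, tab$ti_lower, col = "blue", lty = 1)
  graphics::lines(tab$spike_ng, tab$ti_upper, col = "blue", lty = 1)
  if ("content_lower" %in% names(tab)) {
    graphics::lines(tab$spike_ng, tab$content_lower, col = "darkred",
                    lty = 4)
    graphics::lines(tab$spike_ng, tab$content_upper, col = "darkred",
                    lty = 4)
  }
  graphics::abline(h = c(-x$limit, x$limit), lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3, col = "grey70")
  invisible(x)
}

#' Simulate replicate-block tables from a fitted profile
#'
#' Draws new replicate-block relative errors from the fitted two-level
#' Gaussian hierarchy (between-assay and within-assay components at each
#' level taken from the fitted level statistics, biases from the fitted
#' profile), mirroring the layout of the original data.
#'
#' @param object a `te_profile`.
#' @param nsim number of simulated tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return List of data frames shaped like the input blocks.
#' @export
simulate.te_profile <- function(object, nsim = 1, seed = 1L, ...) {
  blocks <- object$blocks
  ls <- object$level_stats
  with_seed(seed, {
    lapply(seq_len(nsim), function(s) {
      assays <- sort(unique(blocks$assay))
      out <- blocks
      i <- match(out$spike_ng, ls$spike_ng)
      u <- stats::rnorm(length(assays))
      sb <- ls$sigma_B[i]
      e <- stats::rnorm(nrow(out)) * ls$sigma_W[i]
      out$re <- ls$bias[i] + u[match(out$assay, assays)] * sb + e
      out$y_ng <- out$spike_ng * (1 + out$re / 100)
      out
    })
  })
}

#' Residuals of a total-error profile
#'
#' Replicate-block relative errors centred on their level bias.
#'
#' @param object a `te_profile`.
#' @param ... unused.
#' @return Numeric vector of centred relative errors (percent).
#' @export
residuals.te_profile <- function(object, ...) {
  i <- match(object$blocks$spike_ng, object$level_stats$spike_ng)
  object$blocks$re - object$level_stats$bias[i]
}
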