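#' Welch-Satterthwaite effective degrees of freedom
#'
#' Effective degrees of freedom for the total-variance estimator
#' `sigma_T^2 = sigma_W^2 + sigma_B^2` expressed through the ANOVA mean
#' squares `MS_W = sigma_W^2` and `MS_B = sigma_B^2 * m_h + sigma_W^2`:
#' `nu = (c_W MS_W + c_B MS_B)^2 / ((c_W MS_W)^2/df_W + (c_B MS_B)^2/df_B)`
#' with `c_W = 1 - 1/m_h`, `c_B = 1/m_h`, floored at 3. When the
#' between-assay component is truncated to zero or not estimable
#' (`sigma_B = 0` or `df_B = 0`), `nu = max(df_W, 3)`.
#'
#' @param sigma_W,sigma_B within/between-assay SDs (percent scale).
#' @param df_W,df_B degrees of freedom (`df_W >= 1`).
#' @param m_h harmonic-mean replication.
#' @param floor lower bound on the returned df.
#' @return Effective degrees of freedom.
#' @examples
#' satterthwaite_df(2.29, 0.14, 8, 3, 3) # 10.78
#' @export
satterthwaite_df <- function(sigma_W, sigma_B, df_W, df_B, m_h, floor = 3) {
  stopifnot(df_W >= 1, sigma_W >= 0, sigma_B >= 0)
  if (sigma_B == 0 || df_B == 0) return(max(df_W, floor))
  if (m_h <= 1) stop("m_h must exceed 1 when a between-assay component exists")
  ms_w <- sigma_W^2
  ms_b <- sigma_B^2 * m_h + sigma_W^2
  c_w <- 1 - 1 / m_h
  c_b <- 1 / m_h
  nu <- (c_w * ms_w + c_b * ms_b)^2 /
    ((c_w * ms_w)^2 / df_W + (c_b * ms_b)^2 / df_B)
  max(nu, floor)
}

#' Coverage factor for a beta-expectation interval
#'
#' Student-t quantile at `(1 + beta) / 2` with `nu_eff` degrees of freedom.
#'
#' @param nu_eff effective degrees of freedom (>= 1).
#' @param beta coverage probability in (0, 1).
#' @return Coverage factor `K`.
#' @export
coverage_factor <- function(nu_eff, beta = 0.95) {
  stopifnot(nu_eff >= 1, beta > 0, beta < 1)
  stats::qt((1 + beta) / 2, df = nu_eff)
}

#' Beta-expectation tolerance interval
#'
#' `bias +/- K_beta * sigma_pred`: the interval expected to contain a future
#' replicate-block relative error with probability `beta`.
#'
#' @param bias level bias (percent).
#' @param sigma_pred predicted total SD (percent), >= 0.
#' @param nu_eff effective degrees of freedom.
#' @param beta coverage probability.
#' @return List of class `tolerance_interval`: `center`, `lower`, `upper`,
#'   `k`, `nu_eff`, `kind = "beta_expectation"`.
#' @examples
#' beta_expectation_ti(-19.01, 2.72, 8) # [-25.28, -12.74]
#' @export
beta_expectation_ti <- function(bias, sigma_pred, nu_eff, beta = 0.95) {
  stopifnot(sigma_pred >= 0)
  k <- coverage_factor(nu_eff, beta)
  structure(list(center = bias, lower = bias - k * sigma_pred,
                 upper = bias + k * sigma_pred, k = k, nu_eff = nu_eff,
                 kind = "beta_expectation"),
            class = "tolerance_interval")
}

#' @export
print.tolerance_interval <- function(x, digits = 4, ...) {
  cat(sprintf("%s TI: [%s, %s] (center %s)\n", x$kind,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$center, digits = digits)))
  invisible(x)
}

# fast internal WLS of log(sigma) on log(mu), weights w; returns c(a, b)
.loglog_wls <- function(sigma, mu, w) {
  x <- log(mu); y <- log(sigma)
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) return(c(yb, 0))
  b <- sum(w * (x - xb) * (y - yb)) / sxx
  c(yb - b * xb, b)
}

#' 95/95 content tolerance intervals by hierarchical cluster bootstrap
#'
#' For each of `B` outer iterations, assays are resampled with replacement
#' and replicate blocks are resampled with replacement within each sampled
#' assay at each level; per-level bias and variance components and the
#' log-log variance model are refitted on the resample; `M` future errors
#' are simulated per level as `e* = Bias* + Z * sigma_pred*` with
#' `Z ~ N(0, 1)`; the inner half-width is the 95th percentile of
#' `|e* - Bias*|`. The reported half-width `HW` at each level is the 95th
#' percentile of the inner half-widths over the `B` iterations, and the
#' interval is the observed bias `+/- HW`.
#'
#' Levels carried by a single assay contribute their repeatability to the
#' refitted variance model whenever that assay is drawn; their half-width is
#' still defined through the model-predicted SD. At least two distinct
#' assays are required overall.
#'
#' @param blocks replicate-block table (`assay`, `spike_ng`, `re`; `re` is
#'   computed from `y_ng` if absent).
#' @param B outer bootstrap iterations (default 4000).
#' @param M simulated future errors per iteration and level (default 1000).
#' @param seed integer seed.
#' @param content content proportion of the inner interval (default 0.95).
#' @param confidence outer confidence (default 0.95).
#' @return Data frame per level: `spike_ng`, `bias`, `hw`, `lower`, `upper`.
#' @export
content_ti_95_95 <- function(blocks, B = 4000, M = 1000, seed = 1L,
                             content = 0.95, confidence = 0.95) {
  if (B < 100 || M < 100) stop("B and M must each be >= 100")
  if (!"re" %in% names(blocks)) blocks <- relative_errors(blocks)
  assays <- sort(unique(blocks$assay))
  if (length(assays) < 2)
    stop("content tolerance intervals need >= 2 assays")
  levs <- sort(unique(blocks$spike_ng))
  nl <- length(levs)
  # re values indexed by [assay][level]
  re_al <- lapply(assays, function(a) lapply(levs, function(l)
    blocks$re[blocks$assay == a & blocks$spike_ng == l]))
  n_lev <- vapply(levs, function(l) sum(blocks$spike_ng == l), numeric(1))
  obs_bias <- vapply(levs, function(l) mean(blocks$re[blocks$spike_ng == l]),
                     numeric(1))
  a_n <- length(assays)
  hw_inner <- matrix(NA_real_, B, nl)
  with_seed(seed, {
    for (bb in seq_len(B)) {
      samp <- sample.int(a_n, a_n, replace = TRUE)
      sig <- rep(NA_real_, nl)
      nb <- rep(0, nl)
      for (j in seq_len(nl)) {
        gm <- numeric(0); ssw <- 0; m_a <- integer(0)
        vals_all <- numeric(0)
        for (ai in samp) {
          v <- re_al[[ai]][[j]]
          m <- length(v)
          if (m == 0) next
          v <- v[sample.int(m, m, replace = TRUE)]
          gm <- c(gm, mean(v))
          ssw <- ssw + sum((v - mean(v))^2)
          m_a <- c(m_a, m)
          vals_all <- c(vals_all, v)
        }
        a_j <- length(gm)
        n_j <- sum(m_a)
        nb[j] <- n_j
        if (n_j < 2) next
        df_w <- n_j - a_j
        ms_w <- if (df_w > 0) ssw / df_w else 0
        if (a_j >= 2) {
          grand <- sum(gm * m_a) / n_j
          ms_b <- sum(m_a * (gm - grand)^2) / (a_j - 1)
          m_h <- a_j / sum(1 / m_a)
          s_b2 <- max((ms_b - ms_w) / m_h, 0)
        } else s_b2 <- 0
        sig[j] <- sqrt(ms_w + s_b2)
      }
      ok <- which(!is.na(sig) & sig > 0 & nb >= 2)
      if (length(ok) >= 2) {
        ab <- .loglog_wls(sig[ok], levs[ok], nb[ok] - 1)
        sig_pred <- exp(ab[1] + ab[2] * log(levs))
      } else sig_pred <- sig
      for (j in seq_len(nl)) {
        if (is.na(sig_pred[j])) next
        z <- stats::rnorm(M)
        hw_inner[bb, j] <- stats::quantile(abs(z), content) * sig_pred[j]
      }
    }
  })
  hw <- vapply(seq_len(nl), function(j)
    stats::quantile(hw_inner[, j], confidence, na.rm = TRUE), numeric(1))
  data.frame(spike_ng = levs, bias = obs_bias, hw = hw,
             lower = obs_bias - hw, upper = obs_bias + hw)
}

#' Acceptance decision for a tolerance interval
#'
#' Pass iff the interval is contained in the closed set
#' `[-limit, +limit]`.
#'
#' @param lower,upper interval bounds (percent), or a `tolerance_interval`
#'   as `lower` with `upper` missing.
#' @param limit symmetric acceptance limit (percent).
#' @return Logical pass flag.
#' @export
acceptance_decision <- function(lower, upper = NULL, limit = 30) {
  if (inherits(lower, "tolerance_interval")) {
    upper <- lower$upper; lower <- lower$lower
  }
  lower >= -limit & upper <= limit
}

#' Validated range and LLOQ from per-level acceptance decisions
#'
#' The validated range runs from the lowest to the highest passing level and
#' the LLOQ is the lowest passing level, provided the passing levels are
#' contiguous; an interior failure yields a fragmented range with no LLOQ
#' (reported with a warning) unless `allow_fragmented` is set.
#'
#' @param pass logical per-level pass flags (ordered by level).
#' @param spike_ng per-level nominal amounts.
#' @param allow_fragmented report the bounds of the passing set even when it
#'   is not contiguous.
#' @return List: `lower`, `upper` (ng, `NA` if nothing passes), `lloq`,
#'   `fragmented`.
#' @export
validated_range <- function(pass, spike_ng, allow_fragmented = FALSE) {
  stopifnot(length(pass) == length(spike_ng))
  ord <- order(spike_ng)
  pass <- pass[ord]; spike_ng <- spike_ng[ord]
  idx <- which(pass)
  if (length(idx) == 0)
    return(list(lower = NA_real_, upper = NA_real_, lloq = NA_real_,
                fragmented = FALSE))
  contiguous <- all(diff(idx) == 1)
  if (!contiguous && !allow_fragmented) {
    warning("passing levels are not contiguous; range is fragmented and ",
            "no LLOQ is reported without explicit override")
    return(list(lower = NA_real_, upper = NA_real_, lloq = NA_real_,
                fragmented = TRUE))
  }
  list(lower = spike_ng[min(idx)], upper = spike_ng[max(idx)],
       lloq = spike_ng[min(idx)], fragmented = !contiguous)
}
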