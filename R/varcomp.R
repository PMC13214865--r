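#' Relative errors for a table of replicate blocks
#'
#' Adds (or recomputes) the percent relative error
#' `RE = 100 * (Y - mu) / mu` for each replicate block.
#'
#' @param blocks data frame with `y_ng` and `spike_ng`.
#' @return The data frame with an `re` column.
#' @export
relative_errors <- function(blocks) {
  stopifnot(all(c("y_ng", "spike_ng") %in% names(blocks)))
  blocks$re <- relative_error(blocks$y_ng, blocks$spike_ng)
  blocks
}

#' One-way random-effects decomposition by method of moments
#'
#' Decomposes replicate-block relative errors at one spike level into
#' within-assay and between-assay components with assay as the (possibly
#' unbalanced) grouping factor: `MS_within` is the pooled within-group mean
#' square, `MS_between` the between-group mean square,
#' `sigma_B^2 = max((MS_between - MS_within) / m_h, 0)` with harmonic-mean
#' replication `m_h = A / sum(1/m_a)`, and
#' `sigma_T = sqrt(sigma_W^2 + sigma_B^2)`. With a single assay the
#' between-assay component is not estimable (`df_B = 0`) and is set to 0 with
#' `truncated = TRUE`.
#'
#' @param re numeric vector of relative errors (percent).
#' @param assay grouping factor of the same length.
#' @return List: `bias`, `ms_within`, `ms_between`, `df_W`, `df_B`, `m_h`,
#'   `sigma_W`, `sigma_B`, `sigma_T`, `truncated`, `n`, `n_assays`.
#' @export
anova_mom <- function(re, assay) {
  if (length(re) < 2) stop("need >= 2 replicate blocks")
  stopifnot(length(re) == length(assay))
  groups <- split(re, assay)
  a <- length(groups)
  n <- length(re)
  m_a <- lengths(groups)
  grand <- mean(re)
  df_w <- n - a
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  ms_w <- if (df_w > 0) ssw / df_w else 0
  if (a >= 2) {
    df_b <- a - 1
    ms_b <- sum(m_a * (vapply(groups, mean, numeric(1)) - grand)^2) / df_b
    m_h <- a / sum(1 / m_a)
    s_b2 <- max((ms_b - ms_w) / m_h, 0)
    truncated <- ms_b <= ms_w
  } else {
    df_b <- 0L
    ms_b <- NA_real_
    m_h <- m_a[[1]]
    s_b2 <- 0
    truncated <- TRUE
  }
  s_w2 <- ms_w
  list(bias = grand, ms_within = ms_w, ms_between = ms_b,
       df_W = df_w, df_B = df_b, m_h = unname(m_h),
       sigma_W = sqrt(s_w2), sigma_B = sqrt(s_b2),
       sigma_T = sqrt(s_w2 + s_b2), truncated = truncated,
       n = n, n_assays = a)
}

#' Per-level bias and variance components
#'
#' Runs [anova_mom()] on the relative errors of every spike level.
#'
#' @param blocks replicate-block table with `assay`, `spike_ng` and `re`
#'   (added by [relative_errors()] if absent).
#' @return Data frame with one row per level: `spike_ng`, `mean_ng`, `bias`,
#'   `sigma_W`, `sigma_B`, `sigma_T`, `ms_within`, `ms_between`, `df_W`,
#'   `df_B`, `m_h`, `n`, `n_assays`, `truncated`.
#' @export
level_stats <- function(blocks) {
  if (!"re" %in% names(blocks)) blocks <- relative_errors(blocks)
  levs <- sort(unique(blocks$spike_ng))
  rows <- lapply(levs, function(l) {
    sub <- blocks[blocks$spike_ng == l, ]
    st <- anova_mom(sub$re, sub$assay)
    data.frame(spike_ng = l,
               mean_ng = if ("y_ng" %in% names(sub)) mean(sub$y_ng)
                         else NA_real_,
               bias = st$bias, sigma_W = st$sigma_W, sigma_B = st$sigma_B,
               sigma_T = st$sigma_T, ms_within = st$ms_within,
               ms_between = st$ms_between, df_W = st$df_W, df_B = st$df_B,
               m_h = st$m_h, n = st$n, n_assays = st$n_assays,
               truncated = st$truncated)
  })
  do.call(rbind, rows)
}

#' Log-log model of total SD versus spike amount
#'
#' Fits `log(sigma_T) = a + b * log(mu)` by weighted least squares with
#' weights `n_j - 1` (degrees-of-freedom weighting), where `n_j` is the
#' number of replicate-block observations at level `j`. Predictions
#' exponentiate the fitted values and are invariant to the logarithm base.
#' Levels with `sigma_T = 0` are excluded with a warning.
#'
#' @param sigma_T per-level total SDs (percent).
#' @param mu per-level nominal amounts (> 0).
#' @param n per-level replicate-block counts.
#' @return Object of class `variance_model` with coefficients `a`, `b` and a
#'   `predict` method.
#' @export
fit_variance_model <- function(sigma_T, mu, n) {
  stopifnot(length(sigma_T) == length(mu), length(mu) == length(n))
  keep <- sigma_T > 0
  if (any(!keep))
    warning("excluding level(s) with zero total SD: ",
            paste(mu[!keep], collapse = ", "), " ng")
  sigma_T <- sigma_T[keep]; mu <- mu[keep]; n <- n[keep]
  if (length(mu) < 2) stop("need >= 2 levels with positive total SD")
  w <- n - 1
  if (any(w <= 0)) stop("every included level needs n_j >= 2")
  x <- log(mu); y <- log(sigma_T)
  xb <- sum(w * x) / sum(w); yb <- sum(w * y) / sum(w)
  b <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  a <- yb - b * xb
  structure(list(a = a, b = b, mu = mu, sigma_T = sigma_T, weights = w,
                 fitted = exp(a + b * x)),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, digits = 4, ...) {
  cat("log(sigma_T) =", format(x$a, digits = digits), "+",
      format(x$b, digits = digits), "* log(mu)  [weights n_j - 1]\n")
  invisible(x)
}

#' Predicted total SD at given spike amounts
#'
#' @param object a `variance_model`.
#' @param newdata nominal amounts (ng), or a data frame with `spike_ng`.
#' @param ... unused.
#' @return Predicted total SD (percent).
#' @export
predict.variance_model <- function(object, newdata, ...) {
  mu <- if (is.data.frame(newdata)) newdata$spike_ng else newdata
  if (any(mu <= 0)) stop("spike amounts must be > 0")
  exp(object$a + object$b * log(mu))
}
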