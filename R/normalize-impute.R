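#' Median-sweep normalization
#'
#' Shifts each sample's observed log2 values so that all sample medians
#' equal the global target, defined as the median of the pre-normalization
#' sample medians. Removes sample-to-sample loading/depth offsets while
#' leaving within-sample structure untouched; the missingness mask is
#' unchanged.
#'
#' @param m an `IntensityMatrix` on the log2 scale.
#' @return The normalized matrix. Idempotent, and equivariant under adding
#'   a constant to all values.
#' @export
median_sweep <- function(m) {
  stopifnot(inherits(m, "IntensityMatrix"))
  if (m$scale != "log2") stop("`median_sweep` expects log2-scale values")
  v <- values(m)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs == 0))
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[n_obs == 0], collapse = ", "))
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  with_values(m, sweep(v, 2, med - target))
}

#' QRILC imputation parameters
#'
#' @param tune_sigma multiplier (> 0) on the fitted standard deviation used
#'   when drawing imputed values; 1 reproduces the fitted spread.
#' @param fit_quantile_range optional probability interval `c(lo, hi)`
#'   restricting which observed quantiles enter the normal-quantile fit; by
#'   default all observed points (which, under left-censoring, already
#'   occupy the upper quantiles) are used.
#' @param seed integer seed for the truncated draws.
#' @return An `ImputeParams` list.
#' @export
impute_params <- function(tune_sigma = 1, fit_quantile_range = NULL,
                          seed = 1L) {
  if (tune_sigma <= 0) stop("`tune_sigma` must be > 0")
  if (!is.null(fit_quantile_range)) {
    if (length(fit_quantile_range) != 2 || fit_quantile_range[1] <= 0 ||
        fit_quantile_range[2] >= 1 ||
        fit_quantile_range[1] >= fit_quantile_range[2])
      stop("`fit_quantile_range` must be an increasing interval within (0, 1)")
  }
  structure(list(tune_sigma = tune_sigma,
                 fit_quantile_range = fit_quantile_range,
                 seed = as.integer(seed)), class = "ImputeParams")
}

# One column of QRILC: fit N(mu, sigma) to the observed upper quantiles and
# draw the missing cells from the fitted normal truncated above at the
# censoring quantile. Returns the filled column plus the fit record.
qrilc_column <- function(x, tune_sigma, fit_quantile_range) {
  miss <- is.na(x)
  n <- length(x)
  k <- sum(miss)
  if (k == 0)
    return(list(x = x, fit = c(mu = NA, sigma = NA, f = 0, Q = NA,
                               fallback = 0)))
  f <- k / n
  obs <- sort(x[!miss])
  m_obs <- length(obs)
  # Left-censoring pushes the observed values into the upper quantiles of
  # the latent distribution: Blom plotting positions offset by the missing
  # fraction.
  p <- f + (1 - f) * (seq_len(m_obs) - 0.375) / (m_obs + 0.25)
  use <- rep(TRUE, m_obs)
  if (!is.null(fit_quantile_range))
    use <- p >= fit_quantile_range[1] & p <= fit_quantile_range[2]
  z <- stats::qnorm(p[use])
  fit <- stats::lm.fit(cbind(1, z), obs[use])
  mu <- fit$coefficients[[1]]
  sigma <- fit$coefficients[[2]]
  fallback <- 0
  # tolerance: a constant column yields a slope at float-noise level
  if (!is.finite(sigma) || sigma <= 1e-8) {
    # degenerate quantile fit: fall back to half-minimum imputation
    warning("QRILC fit produced sigma <= 0; falling back to half-minimum")
    x[miss] <- min(obs) - 1   # half the minimum intensity, on log2 scale
    return(list(x = x, fit = c(mu = mu, sigma = sigma, f = f, Q = NA,
                               fallback = 1)))
  }
  Q <- mu + sigma * stats::qnorm(f)        # truncation bound: f-quantile of fit
  s <- tune_sigma * sigma
  hi <- stats::pnorm((Q - mu) / s)
  u <- stats::runif(k, 0, hi)
  x[miss] <- mu + s * stats::qnorm(u)
  list(x = x, fit = c(mu = mu, sigma = sigma, f = f, Q = Q, fallback = 0))
}

#' Left-censored imputation via quantile regression (QRILC)
#'
#' Per sample: the sorted observed values are assigned plotting positions
#' `p_i = f + (1 - f) (i - 0.375) / (m + 0.25)` (with `f` the missing
#' fraction), a least-squares fit of the observed values against
#' `qnorm(p_i)` yields the latent mean and standard deviation, and each
#' missing cell is drawn from `N(mu, tune_sigma * sigma)` truncated above
#' at the fitted `f`-quantile `Q = mu + sigma * qnorm(f)` — the imputed
#' values represent the censored lower tail. Observed cells are returned
#' bit-identical.
#'
#' @param m an `IntensityMatrix` (log2 scale); every sample needs at least
#'   10 observed values.
#' @param params an [impute_params()].
#' @return The completed matrix; per-sample fits (`mu`, `sigma`, missing
#'   fraction, truncation bound, fallback flag) are attached as attribute
#'   `"qrilc_fit"`.
#' @export
qrilc_impute <- function(m, params = impute_params()) {
  stopifnot(inherits(m, "IntensityMatrix"), inherits(params, "ImputeParams"))
  v <- values(m)
  n_obs <- colSums(!is.na(v))
  if (any(n_obs < 10))
    stop("sample(s) with fewer than 10 observed values: ",
         paste(colnames(v)[n_obs < 10], collapse = ", "))
  withr::with_seed(params$seed, {
    fits <- matrix(NA_real_, ncol(v), 5,
                   dimnames = list(colnames(v),
                                   c("mu", "sigma", "f", "Q", "fallback")))
    for (j in seq_len(ncol(v))) {
      res <- qrilc_column(v[, j], params$tune_sigma, params$fit_quantile_range)
      v[, j] <- res$x
      fits[j, ] <- res$fit
    }
    out <- with_values(m, v)
    attr(out, "qrilc_fit") <- as.data.frame(fits)
    out
  })
}

#' Half-minimum imputation
#'
#' Simple deterministic baseline: every missing cell in a sample is set to
#' half the sample's minimum observed intensity (minimum minus 1 on the
#' log2 scale).
#'
#' @param m an `IntensityMatrix` (log2 scale).
#' @return The completed matrix.
#' @export
halfmin_impute <- function(m) {
  v <- values(m)
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (any(miss)) v[miss, j] <- min(v[, j], na.rm = TRUE) - 1
  }
  with_values(m, v)
}
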