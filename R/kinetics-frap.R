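#' A FRAP recovery trace
#'
#' Holds the post-bleach samples of one fluorescence-recovery-after-
#' photobleaching experiment together with the prebleach and bleach
#' intensities (and, optionally, a separate full-recovery observation).
#'
#' @param time Post-bleach times in seconds, strictly increasing, > 0.
#' @param intensity Fluorescence at those times (same units as `f_pre`).
#' @param f_pre,f_0 Prebleach and immediately-post-bleach intensities.
#' @param f_max Optional full-recovery observation.
#' @return A `frap_trace`: a tibble (`time`, `intensity`) carrying `f_pre`,
#'   `f_0`, `f_max` as attributes.
#' @export
frap_trace <- function(time, intensity, f_pre, f_0, f_max = NULL) {
  if (length(time) != length(intensity)) {
    stopf("`time` and `intensity` lengths differ")
  }
  if (any(time <= 0) || any(diff(time) <= 0)) {
    stopf("`time` must be positive and strictly increasing")
  }
  if (f_0 > f_pre) stopf("bleach intensity exceeds prebleach intensity")
  out <- tibble::tibble(time = as.numeric(time),
                        intensity = as.numeric(intensity))
  attr(out, "f_pre") <- f_pre
  attr(out, "f_0") <- f_0
  attr(out, "f_max") <- f_max
  class(out) <- unique(c("frap_trace", class(out)))
  out
}

#' Fit a biphasic FRAP recovery
#'
#' Nonlinear least squares of
#' `F(t) = F_inf - A_f exp(-k_fast t) - A_s exp(-k_slow t)` with the
#' amplitude constraint `A_f + A_s = F_inf - F_0`. On sparse sampling grids
#' (6 post-bleach points or fewer) a free biphasic fit is not identifiable,
#' so the fast rate is held at `rate_ratio` times the slow rate; on denser
#' grids the ratio is free (>= 1). Fits use Levenberg-Marquardt with
#' multistart over log-spaced slow rates and both amplitude splits, and a
#' relative SSE tolerance of 1e-10.
#'
#' The reported halftime is that of the slow exchange phase,
#' `t_half = log(2)/k_slow`; the mobile fraction is
#' `M = (F_inf - F_0)/(F_pre - F_0)` (with the fitted plateau by default, or
#' the observed full-recovery intensity via `use_fmax`). `M` outside [0, 1]
#' is clipped and flagged.
#'
#' @param trace A [frap_trace()].
#' @param rate_ratio Fixed `k_fast / k_slow` for the constrained fit;
#'   default 10.
#' @param mode `"auto"` (constrained when <= 6 points), `"constrained"` or
#'   `"free"`.
#' @param use_fmax Use the trace's `f_max` instead of the fitted plateau
#'   for the mobile fraction.
#' @return A `frap_fit` with elements `f_inf`, `a_fast`, `a_slow`, `k_fast`,
#'   `k_slow`, `t_half`, `mobile_fraction`, `clipped`, `sse`, `trace`,
#'   `mode`.
#' @export
fit_frap <- function(trace, rate_ratio = 10, mode = c("auto", "constrained",
                                                      "free"),
                     use_fmax = FALSE) {
  stopifnot(inherits(trace, "frap_trace"))
  mode <- match.arg(mode)
  f_pre <- attr(trace, "f_pre")
  f_0 <- attr(trace, "f_0")
  if (f_pre == f_0) {
    stopf("prebleach equals bleach intensity; mobile fraction is undefined")
  }
  t <- trace$time
  y <- trace$intensity
  n <- length(t)
  if (n < 4L) stopf("need >= 4 post-bleach points, got %d", n)
  if (mode == "auto") mode <- if (n <= 6L) "constrained" else "free"
  if (mode == "free" && n < 6L) {
    stopf("free biphasic fit needs >= 6 post-bleach points, got %d", n)
  }

  # parameterization: plateau f_inf, slow fraction of the recovering
  # amplitude, slow rate (log scale), optionally log(ratio - 1)
  k_grid <- log(2) / exp(seq(log(min(t) / 2), log(max(t) * 4),
                             length.out = 6))
  frac_grid <- c(0.3, 0.7)
  span <- max(y) - f_0
  best <- NULL
  for (k0 in k_grid) {
    for (fr0 in frac_grid) {
      fit <- try_frap_fit(t, y, f_0, f_inf0 = max(y), frac0 = fr0,
                          k0 = k0, rate_ratio = rate_ratio,
                          free = mode == "free")
      if (is.null(fit)) next
      if (is.null(best) || fit$sse < best$sse) best <- fit
    }
  }
  if (is.null(best)) {
    stopf("FRAP fit did not converge from any start (best residual: none)")
  }
  f_inf <- best$f_inf
  denom <- if (use_fmax && !is.null(attr(trace, "f_max"))) {
    attr(trace, "f_max")
  } else {
    f_inf
  }
  mobile <- (denom - f_0) / (f_pre - f_0)
  clipped <- mobile < 0 || mobile > 1
  structure(list(
    f_inf = f_inf, a_fast = best$a_fast, a_slow = best$a_slow,
    k_fast = best$k_fast, k_slow = best$k_slow,
    t_half = log(2) / best$k_slow,
    mobile_fraction = min(max(mobile, 0), 1), clipped = clipped,
    sse = best$sse, trace = trace, mode = mode, rate_ratio = rate_ratio
  ), class = "frap_fit")
}

# one Levenberg-Marquardt attempt; NULL on failure
try_frap_fit <- function(t, y, f_0, f_inf0, frac0, k0, rate_ratio, free) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  resid_fn <- function(par) {
    f_inf <- par[["f_inf"]]
    frac <- stats::plogis(par[["logit_frac"]])
    k_slow <- exp(par[["log_k"]])
    ratio <- if (free) 1 + exp(par[["log_rm1"]]) else rate_ratio
    amp <- f_inf - f_0
    a_slow <- frac * amp
    a_fast <- amp - a_slow
    y - frap_model(t, f_inf, a_fast, a_slow, ratio * k_slow, k_slow)
  }
  par0 <- c(f_inf = f_inf0, logit_frac = stats::qlogis(frac0),
            log_k = log(k0))
  if (free) par0 <- c(par0, log_rm1 = log(rate_ratio - 1))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn, control = ctrl),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  par <- fit$par
  f_inf <- par[["f_inf"]]
  frac <- stats::plogis(par[["logit_frac"]])
  k_slow <- exp(par[["log_k"]])
  ratio <- if (free) 1 + exp(par[["log_rm1"]]) else rate_ratio
  amp <- f_inf - f_0
  list(f_inf = f_inf, a_slow = frac * amp, a_fast = (1 - frac) * amp,
       k_slow = k_slow, k_fast = ratio * k_slow,
       sse = sum(fit$fvec^2))
}

#' Summarize a set of FRAP fits
#'
#' Halftimes are summarized by median and interquartile range, mobile
#' fractions by mean and standard deviation in percent. With a single fit
#' the IQR is 0 and the SD is reported as not available.
#'
#' @param fits List of `frap_fit` objects.
#' @return One-row tibble: `n`, `t_half_median`, `t_half_iqr`,
#'   `mobile_mean_pct`, `mobile_sd_pct`.
#' @export
summarize_frap <- function(fits) {
  if (inherits(fits, "frap_fit")) fits <- list(fits)
  if (length(fits) == 0L) stopf("`fits` is empty")
  th <- vapply(fits, function(f) f$t_half, 0)
  mf <- vapply(fits, function(f) f$mobile_fraction, 0)
  tibble::tibble(
    n = length(fits),
    t_half_median = median(th),
    t_half_iqr = if (length(th) > 1L) IQR(th) else 0,
    mobile_mean_pct = 100 * mean(mf),
    mobile_sd_pct = if (length(mf) > 1L) 100 * sd(mf) else NA_real_
  )
}
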