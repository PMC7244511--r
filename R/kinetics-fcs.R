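#' One-component FCS autocorrelation model
#'
#' `G(tau) = 1 + (1/N) (1 + tau/tauD)^-1 (1 + tau/(S^2 tauD))^-1/2` for free
#' 3D diffusion of one species through a Gaussian confocal volume: `N` is
#' the mean particle number in the volume, `tauD` the diffusion time and `S`
#' the structure parameter (axial/lateral ratio). `G(0) = 1 + 1/N` and
#' `G -> 1` for large lags.
#'
#' @param tau Lag times in seconds (>= 0).
#' @param n Particle number (> 0).
#' @param tau_d Diffusion time in seconds (> 0).
#' @param s Structure parameter (>= 1).
#' @return Numeric vector of autocorrelation values.
#' @export
fcs_model <- function(tau, n, tau_d, s = 5) {
  assert_scalar_num(n, "n", lower = 0, strict = TRUE)
  assert_scalar_num(tau_d, "tau_d", lower = 0, strict = TRUE)
  assert_scalar_num(s, "s", lower = 1)
  1 + (1 / n) / ((1 + tau / tau_d) * sqrt(1 + tau / (s^2 * tau_d)))
}

#' Fit the one-component diffusion model to an FCS curve
#'
#' Levenberg-Marquardt least squares over (N, tauD), with the structure
#' parameter fixed (default) or free, from multistart over log-spaced
#' diffusion times.
#'
#' @param curve Tibble with lag and autocorrelation columns (first two
#'   columns are used; e.g. `lag`, `g` from [simulate_fcs()] or `x`, `y`
#'   from [read_timeseries_csv()]). Needs >= 8 points spanning >= 2 decades
#'   of lag.
#' @param s Structure parameter (fixed value, or starting value if free).
#' @param fix_s Hold the structure parameter fixed; default `TRUE`.
#' @param omega Optional beam waist in meters (from [calibrate_focus()]);
#'   when given, the diffusion coefficient `omega^2 / (4 tauD)` is reported.
#' @return An `fcs_fit`: `n_particles`, `tau_d`, `structure_s`,
#'   `diffusion_coef` (or `NA`), `sse`, `curve`.
#' @export
fit_fcs <- function(curve, s = 5, fix_s = TRUE, omega = NULL) {
  tau <- curve[[1L]]
  g <- curve[[2L]]
  if (length(tau) < 8L) stopf("need >= 8 points, got %d", length(tau))
  pos <- tau[tau > 0]
  if (log10(max(pos) / min(pos)) < 2) {
    stopf("lag grid must span at least two decades")
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  n0 <- 1 / max(max(g) - 1, 1e-6)
  tau_grid <- 10^seq(log10(min(pos)), log10(max(pos)), length.out = 5)
  best <- NULL
  best_sse <- Inf
  for (td0 in tau_grid) {
    resid_fn <- function(par) {
      s_cur <- if (fix_s) s else 1 + exp(par[["log_sm1"]])
      g - fcs_model(tau, n = exp(par[["log_n"]]),
                    tau_d = exp(par[["log_td"]]), s = s_cur)
    }
    par0 <- c(log_n = log(n0), log_td = log(td0))
    if (!fix_s) par0 <- c(par0, log_sm1 = log(max(s - 1, 0.1)))
    fit <- tryCatch(minpack.lm::nls.lm(par = par0, fn = resid_fn,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (sse < best_sse) {
      best <- fit
      best_sse <- sse
    }
  }
  if (is.null(best)) {
    stopf("FCS fit did not converge from any start")
  }
  par <- best$par
  s_hat <- if (fix_s) s else 1 + exp(par[["log_sm1"]])
  tau_d <- exp(par[["log_td"]])
  structure(list(
    n_particles = exp(par[["log_n"]]), tau_d = tau_d, structure_s = s_hat,
    diffusion_coef = if (is.null(omega)) NA_real_ else omega^2 / (4 * tau_d),
    sse = best_sse, curve = curve
  ), class = "fcs_fit")
}

#' Calibrate the confocal volume from a reference dye
#'
#' With a dye of known translational diffusion coefficient, the measured
#' diffusion time gives the lateral beam waist `omega = sqrt(4 D tauD)`;
#' with the structure parameter `S` this defines the axial radius
#' `z0 = S * omega` and the effective volume `pi^(3/2) omega^2 z0`.
#'
#' @param dye_tau_d Measured diffusion time of the calibration dye (s).
#' @param d_ref Reference diffusion coefficient in m^2/s (default 4.0e-10,
#'   a green calibration dye at room temperature).
#' @param s Structure parameter; default 5.
#' @return A list: `omega` (m), `z0` (m), `v_eff` (m^3).
#' @export
calibrate_focus <- function(dye_tau_d, d_ref = 4.0e-10, s = 5) {
  assert_scalar_num(dye_tau_d, "dye_tau_d", lower = 0, strict = TRUE)
  assert_scalar_num(d_ref, "d_ref", lower = 0, strict = TRUE)
  omega <- sqrt(4 * d_ref * dye_tau_d)
  list(omega = omega, z0 = s * omega, v_eff = pi^(3 / 2) * omega^2 *
         (s * omega))
}

#' Competition-binding model for a labeled probe complex
#'
#' Bound fraction of the probe at competitor concentration `c`:
#' `b(c) = b0 (1 + L/Kp) / (1 + L/Kp + c/Kd)` with `L` the unlabeled
#' probe-ligand concentration and `Kp` its dissociation constant. Under the
#' trace-probe assumption (`L = 0`, the default) this reduces to
#' `b0 / (1 + c/Kd)`: `b(0) = b0` and `b -> 0` as `c -> Inf`.
#'
#' @param conc Competitor concentrations (same units as `kd`).
#' @param b0 Baseline bound fraction at zero competitor.
#' @param kd Competitor dissociation constant.
#' @param probe_conc,probe_kd `L` and `Kp` of the exact variant.
#' @return Numeric vector of bound fractions.
#' @export
competition_bound <- function(conc, b0, kd, probe_conc = 0,
                              probe_kd = Inf) {
  if (any(conc < 0)) stopf("concentrations must be >= 0")
  assert_scalar_num(kd, "kd", lower = 0, strict = TRUE)
  lk <- if (is.finite(probe_kd)) probe_conc / probe_kd else 0
  b0 * (1 + lk) / (1 + lk + conc / kd)
}

#' Fit a competition titration for the competitor Kd
#'
#' Levenberg-Marquardt least squares of [competition_bound()] over
#' `(b0, Kd)` with multistart over log-spaced Kd values spanning the
#' titrated concentration range. A titration whose bound fractions span
#' less than a factor of 2 does not bracket the inflection; the fit then
#' warns that the Kd is weakly constrained.
#'
#' @param titration Tibble with concentration and bound-fraction columns
#'   (first two columns are used, e.g. `conc`, `bound`); >= 6 points.
#' @param probe_conc,probe_kd Probe parameters of the exact competition
#'   variant; defaults give the trace-probe model.
#' @return A `binding_fit`: `kd`, `kd_se`, `b0`, `sse`, `titration`.
#' @export
fit_competition <- function(titration, probe_conc = 0, probe_kd = Inf) {
  conc <- titration[[1L]]
  bound <- titration[[2L]]
  if (length(conc) < 6L) {
    stopf("need >= 6 titration points, got %d", length(conc))
  }
  if (any(conc <= 0)) stopf("concentrations must be > 0")
  if (any(bound < -0.2 | bound > 1.2)) {
    stopf("bound fractions must lie in [0, 1] (up to readout noise)")
  }
  pos <- range(bound[bound > 0])
  if (length(pos) == 2L && pos[2L] / max(pos[1L], 1e-12) < 2) {
    warn(paste("bound fractions span less than two-fold;",
               "the titration may not bracket the inflection and the Kd",
               "confidence interval will be wide"))
  }
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  kd_grid <- 10^seq(log10(min(conc)), log10(max(conc)), length.out = 7)
  best <- NULL
  best_fit <- NULL
  for (kd0 in kd_grid) {
    resid_fn <- function(par) {
      bound - competition_bound(conc, b0 = par[["b0"]],
                                kd = exp(par[["log_kd"]]),
                                probe_conc = probe_conc,
                                probe_kd = probe_kd)
    }
    par0 <- c(b0 = max(bound), log_kd = log(kd0))
    fit <- tryCatch(minpack.lm::nls.lm(par = par0, fn = resid_fn,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse)
      best_fit <- fit
    }
  }
  if (is.null(best)) stopf("competition fit did not converge from any start")
  kd <- exp(best$par[["log_kd"]])
  kd_se <- tryCatch({
    v <- vcov(best_fit)
    # delta method from log scale
    kd * sqrt(v["log_kd", "log_kd"])
  }, error = function(e) NA_real_)
  structure(list(
    kd = kd, kd_se = kd_se, b0 = best$par[["b0"]], sse = best$sse,
    titration = tibble::tibble(conc = conc, bound = bound)
  ), class = "binding_fit")
}
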