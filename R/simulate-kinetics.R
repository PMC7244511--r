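#' Specification for synthetic FRAP / FCS / titration data
#'
#' FRAP recoveries follow the biphasic model
#' `F(t) = F_inf - A_f exp(-k_fast t) - A_s exp(-k_slow t)` with
#' `A_f + A_s = F_inf - F_0`; the defaults use the imaging grid of a
#' Z-disc bleaching experiment (5, 20, 60, 120 s plus a full-recovery
#' "max" point), a slow-phase halftime of 33 s, mobile fraction 0.86, a
#' fast:slow rate ratio of 10 and 2% Gaussian readout noise.
#' FCS autocorrelation curves follow the one-component 3D diffusion model
#' `G(tau) = 1 + (1/N) (1 + tau/tauD)^-1 (1 + tau/(S^2 tauD))^-1/2`.
#' Competition titrations follow the trace-probe competition model of
#' [fit_competition()]; concentrations are in micromolar.
#'
#' @param f_pre,f_0 Prebleach and bleach intensities (arbitrary units).
#' @param mobile_fraction Mobile fraction, sets the plateau
#'   `F_inf = F_0 + M (F_pre - F_0)`.
#' @param halftime Slow-phase halftime in seconds (`k_slow = log(2)/t_half`).
#' @param rate_ratio `k_fast / k_slow` (> 1).
#' @param frac_fast Fraction of the recovering amplitude in the fast phase.
#' @param times Post-bleach sampling times in seconds (strictly increasing).
#' @param plateau_time Time of the full-recovery observation in seconds
#'   (`NULL` to omit).
#' @param frap_noise_sd Gaussian noise SD as a fraction of `f_pre`.
#' @param n_traces Number of FRAP traces to generate.
#' @param n_particles,tau_d,structure_s FCS particle number, diffusion time
#'   (s) and structure parameter.
#' @param lags Lag grid in seconds for the autocorrelation curve.
#' @param fcs_noise_sd Additive noise SD on `G`.
#' @param b0 Baseline bound fraction of the titration (no competitor).
#' @param competitor_kd Ground-truth competitor dissociation constant (uM).
#' @param conc Competitor concentration grid in uM (any order; > 0).
#' @param titration_noise_sd Readout noise SD on the bound fraction.
#' @param probe_conc,probe_kd Unlabeled probe-ligand concentration and probe
#'   Kd (uM) for the exact competition variant; the trace-probe default
#'   (`probe_conc = 0`) reduces to `b0 / (1 + c/Kd)`.
#' @param seed Integer seed.
#' @return A `kinetic_sim_spec` (named list).
#' @export
kinetic_sim_spec <- function(f_pre = 1, f_0 = 0.2, mobile_fraction = 0.86,
                             halftime = 33, rate_ratio = 10, frac_fast = 0.3,
                             times = c(5, 20, 60, 120), plateau_time = 360,
                             frap_noise_sd = 0.02, n_traces = 20L,
                             n_particles = 5, tau_d = 1e-4, structure_s = 5,
                             lags = 10^seq(-6, 0, length.out = 64),
                             fcs_noise_sd = 0,
                             b0 = 0.8, competitor_kd = 1.17,
                             conc = 10^seq(log10(0.021), log10(44),
                                           length.out = 12),
                             titration_noise_sd = 0.03,
                             probe_conc = 0, probe_kd = 0.5,
                             seed = 1L) {
  if (f_0 > f_pre) stopf("`f_0` must not exceed `f_pre`")
  assert_scalar_num(mobile_fraction, "mobile_fraction", lower = 0, upper = 1)
  assert_scalar_num(halftime, "halftime", lower = 0, strict = TRUE)
  assert_scalar_num(rate_ratio, "rate_ratio", lower = 1, strict = TRUE)
  assert_scalar_num(frac_fast, "frac_fast", lower = 0, upper = 1)
  if (any(diff(times) <= 0) || any(times <= 0)) {
    stopf("`times` must be positive and strictly increasing")
  }
  assert_scalar_num(n_particles, "n_particles", lower = 0, strict = TRUE)
  assert_scalar_num(tau_d, "tau_d", lower = 0, strict = TRUE)
  assert_scalar_num(structure_s, "structure_s", lower = 1)
  assert_scalar_num(competitor_kd, "competitor_kd", lower = 0, strict = TRUE)
  assert_scalar_num(b0, "b0", lower = 0, upper = 1)
  if (any(conc <= 0)) stopf("all concentrations must be > 0")
  structure(list(
    f_pre = f_pre, f_0 = f_0, mobile_fraction = mobile_fraction,
    halftime = halftime, rate_ratio = rate_ratio, frac_fast = frac_fast,
    times = times, plateau_time = plateau_time,
    frap_noise_sd = frap_noise_sd, n_traces = as.integer(n_traces),
    n_particles = n_particles, tau_d = tau_d, structure_s = structure_s,
    lags = lags, fcs_noise_sd = fcs_noise_sd,
    b0 = b0, competitor_kd = competitor_kd, conc = sort(conc),
    titration_noise_sd = titration_noise_sd,
    probe_conc = probe_conc, probe_kd = probe_kd,
    seed = as.integer(seed)
  ), class = "kinetic_sim_spec")
}

# noiseless biphasic recovery
frap_model <- function(t, f_inf, a_fast, a_slow, k_fast, k_slow) {
  f_inf - a_fast * exp(-k_fast * t) - a_slow * exp(-k_slow * t)
}

#' Simulate FRAP recovery traces
#'
#' Each trace holds the prebleach and bleach intensities plus noisy samples
#' of the biphasic recovery at the spec's post-bleach times (including the
#' full-recovery point when `plateau_time` is set).
#'
#' @param spec A [kinetic_sim_spec()].
#' @return A list of [frap_trace()] objects of length `spec$n_traces`.
#' @export
simulate_frap <- function(spec) {
  stopifnot(inherits(spec, "kinetic_sim_spec"))
  k_slow <- log(2) / spec$halftime
  k_fast <- spec$rate_ratio * k_slow
  f_inf <- spec$f_0 + spec$mobile_fraction * (spec$f_pre - spec$f_0)
  amp <- f_inf - spec$f_0
  a_fast <- spec$frac_fast * amp
  a_slow <- amp - a_fast
  times <- c(spec$times, spec$plateau_time)
  clean <- frap_model(times, f_inf, a_fast, a_slow, k_fast, k_slow)
  with_seed_opt(spec$seed, {
    lapply(seq_len(spec$n_traces), function(i) {
      noisy <- clean + rnorm(length(clean), sd = spec$frap_noise_sd * spec$f_pre)
      f_pre_obs <- spec$f_pre + rnorm(1, sd = spec$frap_noise_sd * spec$f_pre)
      f_0_obs <- spec$f_0 + rnorm(1, sd = spec$frap_noise_sd * spec$f_pre)
      frap_trace(time = times, intensity = noisy,
                 f_pre = f_pre_obs, f_0 = f_0_obs)
    })
  })
}

#' Simulate FCS autocorrelation curves and a competition titration
#'
#' The autocorrelation curve follows the one-component 3D diffusion model
#' (see [fcs_model()]); the titration follows the competition-binding model
#' of [fit_competition()] with the spec's probe and competitor parameters.
#'
#' @param spec A [kinetic_sim_spec()].
#' @param n_curves Number of autocorrelation curves.
#' @return A list with `curves` (list of tibbles `lag`, `g`) and `titration`
#'   (tibble `conc` in uM, `bound`).
#' @export
simulate_fcs <- function(spec, n_curves = 1L) {
  stopifnot(inherits(spec, "kinetic_sim_spec"))
  clean_g <- fcs_model(spec$lags, n = spec$n_particles, tau_d = spec$tau_d,
                       s = spec$structure_s)
  clean_b <- competition_bound(spec$conc, b0 = spec$b0,
                               kd = spec$competitor_kd,
                               probe_conc = spec$probe_conc,
                               probe_kd = spec$probe_kd)
  with_seed_opt(spec$seed, {
    curves <- lapply(seq_len(n_curves), function(i) {
      tibble::tibble(lag = spec$lags,
                     g = clean_g + rnorm(length(clean_g),
                                         sd = spec$fcs_noise_sd))
    })
    titration <- tibble::tibble(
      conc = spec$conc,
      bound = clean_b + rnorm(length(clean_b), sd = spec$titration_noise_sd)
    )
    list(curves = curves, titration = titration)
  })
}
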