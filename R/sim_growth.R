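#' Parameters for a simulated growth/respiration assay
#'
#' Bundles the ground-truth physiology and the measurement setup of one
#' simulated batch-culture CUE assay. Biomass follows three phases: a flat lag,
#' exact exponential growth at rate `mu_true`, and a logistic approach to
#' `od_max` once half the carrying capacity is reached. The mass-specific
#' respiration rate implied by the ground truth is
#' `R_true = mu_true * (1 - cue_true) / cue_true`, so that
#' `CUE = mu / (mu + R)` recovers `cue_true` exactly on noiseless data.
#'
#' @param mu_true Intrinsic growth rate, per hour. Must be positive.
#' @param cue_true Ground-truth carbon use efficiency in (0, 1].
#' @param od_start,od_max Starting and saturating optical density (OD600).
#' @param lag_h Lag phase duration, hours.
#' @param duration_h Total assay duration, hours.
#' @param read_interval_h Time between reads, hours.
#' @param od_noise_sd Standard deviation of multiplicative log-normal OD read
#'   noise (measurement error grows with signal).
#' @param co2_noise_sd Standard deviation of additive Gaussian CO2 read noise,
#'   ppm.
#' @param headspace_ml,culture_ml Headspace and culture volumes, ml.
#' @param temperature_c Assay temperature, degrees Celsius (used for the
#'   ideal-gas ppm conversion).
#' @param baseline_ppm Ambient CO2 concentration at the first read, ppm.
#' @param seed Optional RNG seed for reproducible noise.
#'
#' @return A validated list of class `growth_sim_params`.
#' @export
#' @examples
#' p <- growth_sim_params(mu_true = 0.3, cue_true = 0.6, od_noise_sd = 0)
#' curves <- simulate_growth_experiment(p, n_replicates = 2)
growth_sim_params <- function(mu_true = 0.3,
                              cue_true = 0.6,
                              od_start = 0.02,
                              od_max = 0.8,
                              lag_h = 2,
                              duration_h = 24,
                              read_interval_h = 1,
                              od_noise_sd = 0.01,
                              co2_noise_sd = 5,
                              headspace_ml = 25,
                              culture_ml = 10,
                              temperature_c = 20,
                              baseline_ppm = 415,
                              seed = NULL) {
  check_number(mu_true, "mu_true", min = 0, allow_min = FALSE)
  check_number(cue_true, "cue_true", min = 0, max = 1, allow_min = FALSE)
  check_number(od_start, "od_start", min = 0, allow_min = FALSE)
  check_number(od_max, "od_max", min = od_start, allow_min = FALSE)
  check_number(lag_h, "lag_h", min = 0)
  check_number(duration_h, "duration_h", min = 0, allow_min = FALSE)
  check_number(read_interval_h, "read_interval_h", min = 0, allow_min = FALSE)
  check_number(od_noise_sd, "od_noise_sd", min = 0)
  check_number(co2_noise_sd, "co2_noise_sd", min = 0)
  check_number(headspace_ml, "headspace_ml", min = 0, allow_min = FALSE)
  check_number(culture_ml, "culture_ml", min = 0, allow_min = FALSE)
  check_number(temperature_c, "temperature_c", min = -273.15, allow_min = FALSE)
  check_number(baseline_ppm, "baseline_ppm", min = 0)
  structure(
    list(
      mu_true = mu_true, cue_true = cue_true,
      r_true = mu_true * (1 - cue_true) / cue_true,
      od_start = od_start, od_max = od_max, lag_h = lag_h,
      duration_h = duration_h, read_interval_h = read_interval_h,
      od_noise_sd = od_noise_sd, co2_noise_sd = co2_noise_sd,
      headspace_ml = headspace_ml, culture_ml = culture_ml,
      temperature_c = temperature_c, baseline_ppm = baseline_ppm,
      seed = seed
    ),
    class = "growth_sim_params"
  )
}

# Noise-free biomass trajectory (OD units). Lag -> exponential -> logistic,
# switching to logistic once OD reaches od_max / 2.
sim_true_od <- function(time_h, p) {
  od_switch <- p$od_max / 2
  # time (after lag) at which the exponential trajectory reaches the switch OD
  tau_switch <- if (p$od_start >= od_switch) 0 else log(od_switch / p$od_start) / p$mu_true
  tau <- pmax(time_h - p$lag_h, 0)
  od <- ifelse(
    tau <= tau_switch,
    p$od_start * exp(p$mu_true * tau),
    {
      e <- exp(p$mu_true * (tau - tau_switch))
      p$od_max * e / (1 + e) # logistic continuation from od_max / 2
    }
  )
  od
}

# Closed-form integral of the biomass trajectory from 0 to each time point,
# in OD * hours. Used so the noiseless cumulative CO2 is exact.
sim_true_od_integral <- function(time_h, p) {
  od_switch <- p$od_max / 2
  tau_switch <- if (p$od_start >= od_switch) 0 else log(od_switch / p$od_start) / p$mu_true
  mu <- p$mu_true
  int_exp_to <- function(tau) p$od_start * (exp(mu * tau) - 1) / mu
  int_at_switch <- int_exp_to(tau_switch)
  vapply(time_h, function(t) {
    lag_part <- p$od_start * min(t, p$lag_h)
    tau <- max(t - p$lag_h, 0)
    growth_part <- if (tau <= tau_switch) {
      int_exp_to(tau)
    } else {
      # integral of od_max * e/(1+e) with e = exp(mu (tau - tau_switch))
      int_at_switch +
        (p$od_max / mu) * log((1 + exp(mu * (tau - tau_switch))) / 2)
    }
    lag_part + growth_part
  }, numeric(1))
}

# micrograms of CO2 carbon -> added headspace ppm by the ideal gas law
co2c_ug_to_ppm <- function(co2c_ug, headspace_ml, temperature_c) {
  t_k <- temperature_c + 273.15
  total_umol <- 101325 * (headspace_ml * 1e-6) / (8.314462618 * t_k) * 1e6
  umol_co2 <- co2c_ug / 12.011
  umol_co2 / total_umol * 1e6
}

#' Simulate replicated growth curves with known CUE
#'
#' Generates per-replicate OD600 and headspace CO2 time series from the
#' three-phase growth model in [growth_sim_params()]. Cumulative respired
#' carbon is the exact integral of `R_true * biomass` over time, converted to
#' headspace ppm at the assay temperature; OD noise is multiplicative
#' log-normal and CO2 noise additive Gaussian.
#'
#' @param params A [growth_sim_params()] object.
#' @param n_replicates Number of replicate cultures to simulate.
#' @param isolate,substrate Labels attached to the output rows.
#' @param biomass_per_od Biomass conversion factor used to express respired
#'   carbon on the biomass-carbon scale (ug C per OD unit per ml); only the
#'   product with `culture_ml` matters for the emitted ppm.
#'
#' @return A tibble with columns `isolate`, `substrate`, `temperature_c`,
#'   `replicate`, `time_h`, `od600`, `co2_ppm`. The per-replicate ground truth
#'   (`mu_true`, `r_true`, `cue_true`) is attached as attribute `"truth"` and
#'   retrievable with [growth_truth()].
#' @export
simulate_growth_experiment <- function(params, n_replicates = 3,
                                       isolate = "sim", substrate = "glucose",
                                       biomass_per_od = 130) {
  if (!inherits(params, "growth_sim_params")) {
    abort_bad_arg("`params` must come from growth_sim_params().")
  }
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1L)
  p <- params
  time_h <- seq(0, p$duration_h, by = p$read_interval_h)
  od_true <- sim_true_od(time_h, p)
  # cumulative respired carbon, ug C per culture
  biomass_int <- sim_true_od_integral(time_h, p) * biomass_per_od * p$culture_ml
  co2c_true <- p$r_true * biomass_int
  ppm_true <- p$baseline_ppm +
    co2c_ug_to_ppm(co2c_true, p$headspace_ml, p$temperature_c)

  curves <- with_seed(p$seed, {
    purrr::map(seq_len(n_replicates), function(rep) {
      od_obs <- od_true * exp(rnorm(length(time_h), 0, p$od_noise_sd))
      ppm_obs <- ppm_true + rnorm(length(time_h), 0, p$co2_noise_sd)
      tibble(
        isolate = isolate, substrate = substrate,
        temperature_c = p$temperature_c,
        replicate = sprintf("rep%d", rep),
        time_h = time_h, od600 = od_obs, co2_ppm = ppm_obs
      )
    }) |> purrr::list_rbind()
  })

  truth <- tibble(
    isolate = isolate, substrate = substrate, temperature_c = p$temperature_c,
    replicate = sprintf("rep%d", seq_len(n_replicates)),
    mu_true = p$mu_true, r_true = p$r_true, cue_true = p$cue_true
  )
  attr(curves, "truth") <- truth
  curves
}

#' Ground truth attached to a simulated growth experiment
#'
#' @param curves Output of [simulate_growth_experiment()].
#' @return A tibble of per-replicate `mu_true`, `r_true`, `cue_true`.
#' @export
growth_truth <- function(curves) {
  truth <- attr(curves, "truth")
  if (is.null(truth)) abort_bad_arg("no ground truth attached to this object.")
  truth
}
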