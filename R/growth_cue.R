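#' Assay constants for CUE estimation
#'
#' Physical constants of the growth assay: the OD-to-biomass-carbon conversion
#' factor, culture and headspace volumes, and a substrate table used by
#' [energy_per_carbon()]. The conversion factor follows the convention of
#' 130 ug biomass C per OD600 unit per ml of culture (BioNumber 109836); CUE
#' itself only requires that biomass carbon and respired carbon share a mass
#' unit, so the factor cancels out of `mu` and enters CUE only through the
#' biomass scale of `R`.
#'
#' @param biomass_per_od ug biomass C per OD600 unit per ml culture.
#' @param culture_ml,headspace_ml Culture and headspace volumes, ml.
#' @param substrate_table Data frame with columns `substrate`,
#'   `heat_combustion_kj_mol` and `n_carbon`. Defaults to glucose, pyruvate
#'   and succinate with standard heats of combustion.
#' @return A list of class `assay_constants`.
#' @export
assay_constants <- function(biomass_per_od = 130,
                            culture_ml = 10,
                            headspace_ml = 25,
                            substrate_table = default_substrate_table()) {
  check_number(biomass_per_od, "biomass_per_od", min = 0, allow_min = FALSE)
  check_number(culture_ml, "culture_ml", min = 0, allow_min = FALSE)
  check_number(headspace_ml, "headspace_ml", min = 0, allow_min = FALSE)
  stopifnot(all(c("substrate", "heat_combustion_kj_mol", "n_carbon") %in%
                  names(substrate_table)))
  structure(
    list(
      biomass_per_od = biomass_per_od,
      culture_ml = culture_ml,
      headspace_ml = headspace_ml,
      substrate_table = as_tibble(substrate_table)
    ),
    class = "assay_constants"
  )
}

#' @rdname assay_constants
#' @export
default_substrate_table <- function() {
  tibble(
    substrate = c("glucose", "pyruvate", "succinate"),
    heat_combustion_kj_mol = c(2805, 1168, 1491),
    n_carbon = c(6, 3, 4)
  )
}

#' Locate the exponential-growth window of a curve
#'
#' Finds the contiguous run of 3 to 10 time points whose least-squares slope
#' of log biomass against time is maximal, i.e. the exponential phase. Ties
#' (within a relative tolerance of 1e-9) are broken in favour of the longer
#' window, then the earlier start, so a perfectly log-linear series returns
#' the longest admissible window.
#'
#' @param time_h Strictly increasing time points, hours.
#' @param ln_biomass Natural log of biomass (or OD; the window and slope are
#'   identical because the OD-to-biomass conversion is linear).
#' @param min_pts,max_pts Window length bounds (inclusive).
#' @return A list with `start`, `end` (indices), `n` and `slope`.
#' @export
find_exponential_window <- function(time_h, ln_biomass,
                                    min_pts = 3, max_pts = 10) {
  min_pts <- check_count(min_pts, "min_pts", min = 2L)
  max_pts <- check_count(max_pts, "max_pts", min = min_pts)
  ok <- is.finite(time_h) & is.finite(ln_biomass)
  if (any(!ok)) {
    time_h <- time_h[ok]
    ln_biomass <- ln_biomass[ok]
  }
  n <- length(time_h)
  if (n < min_pts) abort_bad_arg(sprintf("need at least %d finite points.", min_pts))
  if (any(diff(time_h) <= 0)) abort_bad_arg("`time_h` must be strictly increasing.")

  best <- list(start = NA_integer_, end = NA_integer_, n = 0L, slope = -Inf)
  # longer windows first, then earlier starts, so strict ">" encodes the
  # tie-break (longest, then earliest)
  for (len in seq(min(max_pts, n), min_pts)) {
    for (start in seq_len(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      tt <- time_h[idx]
      yy <- ln_biomass[idx]
      slope <- stats::cov(tt, yy) / stats::var(tt)
      tol <- 1e-9 * max(1, abs(best$slope))
      if (!is.finite(best$slope) || slope > best$slope + tol) {
        best <- list(start = start, end = start + len - 1L,
                     n = len, slope = slope)
      }
    }
  }
  best
}

#' Convert OD600 to biomass carbon
#'
#' `biomass_C (ug) = od600 * biomass_per_od * culture_ml`.
#'
#' @param od600 Optical density values (must be non-negative).
#' @param constants An [assay_constants()] object.
#' @return Biomass carbon, ug per culture.
#' @export
od_to_biomass_c <- function(od600, constants) {
  if (any(od600 < 0, na.rm = TRUE)) abort_bad_arg("negative OD600.")
  od600 * constants$biomass_per_od * constants$culture_ml
}

#' Convert headspace CO2 ppm to cumulative respired carbon
#'
#' Converts concentration above the first read (the baseline) to micrograms of
#' CO2 carbon via the ideal gas law at the assay temperature and the
#' configured headspace volume.
#'
#' @param co2_ppm Headspace CO2 concentrations, ppm; the first element is the
#'   baseline unless `baseline_ppm` is given.
#' @param constants An [assay_constants()] object.
#' @param temperature_c Assay temperature, degrees Celsius.
#' @param baseline_ppm Optional explicit baseline; defaults to `co2_ppm[1]`.
#' @return Cumulative CO2-C, ug.
#' @export
co2_to_carbon <- function(co2_ppm, constants, temperature_c,
                          baseline_ppm = NULL) {
  if (constants$headspace_ml <= 0) abort_bad_arg("non-positive headspace volume.")
  if (any(co2_ppm < 0, na.rm = TRUE)) abort_bad_arg("negative CO2 ppm.")
  base <- baseline_ppm %||% co2_ppm[1]
  t_k <- temperature_c + 273.15
  total_umol <- 101325 * (constants$headspace_ml * 1e-6) /
    (8.314462618 * t_k) * 1e6
  umol_co2 <- (co2_ppm - base) / 1e6 * total_umol
  umol_co2 * 12.011
}

#' Carbon use efficiency from growth and respiration rates
#'
#' `CUE = mu / (mu + R)`: the fraction of processed carbon allocated to new
#' biomass rather than respired.
#'
#' @param mu Intrinsic growth rate, per hour (positive).
#' @param r Mass-specific respiration rate, per hour (non-negative).
#' @return CUE in (0, 1].
#' @export
compute_cue <- function(mu, r) {
  if (any(mu <= 0, na.rm = TRUE)) abort_bad_arg("`mu` must be positive.")
  if (any(r < 0, na.rm = TRUE)) abort_bad_arg("`r` must be non-negative.")
  mu / (mu + r)
}

# slope, F-test p (single regressor: F = t^2 with 1 and n-2 df), for y ~ x
slope_f_test <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) return(list(slope = NA_real_, p = NA_real_))
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  fitted <- mean(y) + slope * (x - mean(x))
  rss <- sum((y - fitted)^2)
  if (n <= 2) return(list(slope = slope, p = NA_real_))
  if (rss < 1e-300) {
    # perfect fit: a zero slope with zero noise carries no evidence against
    # the null, a nonzero one is unambiguous
    return(list(slope = slope, p = if (abs(slope) < 1e-300) 1 else 0))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- slope / se
  list(slope = slope, p = 2 * pt(-abs(tval), df = n - 2))
}

#' Fit exponential-phase growth and respiration rates for one replicate
#'
#' Finds the exponential window on log biomass carbon, estimates `mu` as its
#' OLS slope, and estimates the mass-specific respiration rate `R` over the
#' same window. The default estimator regresses cumulative CO2-C on biomass C:
#' under exponential growth `dCO2C/dt = R * B`, so that regression is linear
#' with slope `R / mu` exactly, making the estimator exact on noiseless curves
#' and robust to read-time jitter. The alternative `"interval"` estimator
#' averages per-interval `dCO2C/dt` divided by the interval geometric-mean
#' biomass. Both slopes carry single-regressor F-test p values used by the
#' QC rule.
#'
#' @param curve Tibble for one replicate with columns `time_h`, `od600`,
#'   `co2_ppm` and (for the ppm conversion) `temperature_c`.
#' @param constants An [assay_constants()] object.
#' @param method Respiration estimator, `"cumulative"` (default) or
#'   `"interval"`.
#' @param min_pts,max_pts Passed to [find_exponential_window()].
#' @return One-row tibble: window bounds, `mu`, `mu_p`, `r`, `r_p`, `cue`.
#' @export
fit_exponential_rates <- function(curve, constants = assay_constants(),
                                  method = c("cumulative", "interval"),
                                  min_pts = 3, max_pts = 10) {
  method <- match.arg(method)
  stopifnot(all(c("time_h", "od600", "co2_ppm") %in% names(curve)))
  curve <- dplyr::arrange(curve, .data$time_h)
  temperature_c <- if ("temperature_c" %in% names(curve)) {
    curve$temperature_c[1]
  } else 20
  biomass <- od_to_biomass_c(curve$od600, constants)
  co2c <- co2_to_carbon(curve$co2_ppm, constants, temperature_c)
  win <- find_exponential_window(curve$time_h, log(biomass),
                                 min_pts = min_pts, max_pts = max_pts)
  idx <- win$start:win$end
  tt <- curve$time_h[idx]
  bb <- biomass[idx]
  cc <- co2c[idx]

  mu_fit <- slope_f_test(tt, log(bb))
  mu <- mu_fit$slope

  if (method == "cumulative") {
    r_fit <- slope_f_test(bb, cc)
    r <- r_fit$slope * mu
    r_p <- r_fit$p
  } else {
    dt <- diff(tt)
    rates <- diff(cc) / dt / sqrt(bb[-length(bb)] * bb[-1])
    r <- mean(rates)
    # F test of the cumulative-CO2 slope over time as significance reference
    r_fit <- slope_f_test(tt, cc)
    r_p <- r_fit$p
  }

  cue <- if (is.finite(mu) && mu > 0 && is.finite(r) && r >= 0) {
    compute_cue(mu, r)
  } else if (is.finite(mu) && mu > 0 && is.finite(r)) {
    # slightly negative respiration slopes arise from read noise; CUE is
    # reported but capped at 1 and flagged by the r_p filter downstream
    1
  } else {
    NA_real_
  }

  tibble(
    window_start = win$start, window_end = win$end, window_n = win$n,
    mu = mu, mu_p = mu_fit$p, r = r, r_p = r_p, cue = cue
  )
}

#' Estimate CUE for every replicate in a growth table
#'
#' Applies [fit_exponential_rates()] to each (isolate, substrate,
#' temperature_c, replicate) group of a tidy growth table.
#'
#' @param growth_data Tibble with columns `isolate`, `substrate`,
#'   `temperature_c`, `replicate`, `time_h`, `od600`, `co2_ppm`.
#' @inheritParams fit_exponential_rates
#' @return Per-replicate tibble of rates, p values and CUE.
#' @export
estimate_cue <- function(growth_data, constants = assay_constants(),
                         method = c("cumulative", "interval"),
                         min_pts = 3, max_pts = 10) {
  method <- match.arg(method)
  keys <- c("isolate", "substrate", "temperature_c", "replicate")
  stopifnot(all(keys %in% names(growth_data)))
  growth_data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ fit_exponential_rates(
      .x, constants = constants, method = method,
      min_pts = min_pts, max_pts = max_pts
    )) |>
    dplyr::ungroup()
}

#' Quality-control filter for CUE records
#'
#' Drops replicates whose growth or respiration slope does not differ from
#' zero (F test p > `alpha`), then drops whole conditions retaining fewer than
#' `min_replicates` surviving replicates.
#'
#' @param records Output of [estimate_cue()].
#' @param min_replicates Minimum surviving replicates per (isolate, substrate,
#'   temperature) condition.
#' @param alpha Significance level of the slope F tests.
#' @return The retained records with a `qc_pass` column (all `TRUE`).
#' @export
qc_filter <- function(records, min_replicates = 2, alpha = 0.05) {
  min_replicates <- check_count(min_replicates, "min_replicates", min = 1L)
  records |>
    dplyr::filter(
      is.finite(.data$mu_p), is.finite(.data$r_p),
      .data$mu_p <= alpha, .data$r_p <= alpha,
      is.finite(.data$cue)
    ) |>
    dplyr::group_by(.data$isolate, .data$substrate, .data$temperature_c) |>
    dplyr::filter(dplyr::n() >= min_replicates) |>
    dplyr::ungroup() |>
    dplyr::mutate(qc_pass = TRUE)
}

#' Substrate energy content per mole of carbon
#'
#' Heat of combustion divided by the number of carbon atoms per molecule, a
#' substrate-quality axis for CUE comparisons.
#'
#' @param substrate Substrate name present in the constants' substrate table.
#' @param constants An [assay_constants()] object.
#' @return kJ per mol C.
#' @export
energy_per_carbon <- function(substrate, constants = assay_constants()) {
  tbl <- constants$substrate_table
  hit <- match(substrate, tbl$substrate)
  if (anyNA(hit)) {
    abort_bad_arg(sprintf(
      "unknown substrate(s): %s",
      paste(substrate[is.na(hit)], collapse = ", ")
    ))
  }
  if (any(tbl$n_carbon[hit] <= 0)) abort_bad_arg("non-positive carbon count.")
  tbl$heat_combustion_kj_mol[hit] / tbl$n_carbon[hit]
}
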