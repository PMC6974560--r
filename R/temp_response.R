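#' Q10 temperature coefficient
#'
#' The multiplicative change in a quantity per 10 degree C increase:
#' `(v_high / v_low) ^ (10 / (t_high - t_low))`.
#'
#' @param cue_low,cue_high Positive values (here, CUE) at the two
#'   temperatures.
#' @param t_low,t_high Temperatures, degrees C, with `t_high > t_low`.
#' @return The Q10 value (vectorised).
#' @export
q10 <- function(cue_low, t_low, cue_high, t_high) {
  if (any(t_high <= t_low)) abort_bad_arg("`t_high` must exceed `t_low`.")
  if (any(cue_low <= 0 | cue_high <= 0, na.rm = TRUE)) {
    abort_bad_arg("CUE values must be positive.")
  }
  (cue_high / cue_low)^(10 / (t_high - t_low))
}

#' Fractional change in CUE implied by a Q10 over a temperature step
#'
#' `q10 ^ (delta_t / 10) - 1`: e.g. a Q10 of 0.49 over a 10 degree step is a
#' halving (about -51%).
#'
#' @param q10 Q10 value (positive).
#' @param delta_t Temperature change, degrees C.
#' @return Fractional change (0 means no change).
#' @export
cue_change_fraction <- function(q10, delta_t) {
  if (any(q10 <= 0, na.rm = TRUE)) abort_bad_arg("`q10` must be positive.")
  q10^(delta_t / 10) - 1
}

#' Q10 from all replicate pairs across two temperatures
#'
#' Computes Q10 for every cross-pairing of replicates at the two
#' temperatures. Because Q10 is a nonlinear function of the two CUE values,
#' the point estimate is the Q10 of the two replicate means; the pairwise
#' values supply the standard error (standard deviation of pairwise Q10s
#' divided by the square root of the number of pairs). The mean of the
#' pairwise Q10 values is also reported.
#'
#' @param replicates_low,replicates_high Positive CUE replicate values at the
#'   lower and higher temperature.
#' @param t_low,t_high Temperatures, degrees C.
#' @return One-row tibble: `q10` (of means), `q10_pairwise_mean`, `se`
#'   (NA with a single pair), `n_pairs`.
#' @export
q10_all_pairs <- function(replicates_low, replicates_high, t_low, t_high) {
  if (!length(replicates_low) || !length(replicates_high)) {
    abort_bad_arg("need at least one replicate per temperature.")
  }
  pairs <- q10(rep(replicates_low, times = length(replicates_high)), t_low,
               rep(replicates_high, each = length(replicates_low)), t_high)
  n_pairs <- length(pairs)
  tibble(
    q10 = q10(mean(replicates_low), t_low, mean(replicates_high), t_high),
    q10_pairwise_mean = mean(pairs),
    se = if (n_pairs > 1) sd(pairs) / sqrt(n_pairs) else NA_real_,
    n_pairs = n_pairs
  )
}

#' Bootstrap confidence interval for Q10
#'
#' Resamples replicates with replacement within each temperature, recomputes
#' the mean-based Q10 for each resample, and reports the percentile 95%
#' interval. The condition is classified as temperature sensitive when the
#' interval excludes 1. With fewer than 2 replicates at either temperature
#' only the point estimate is returned and `sensitive` is `NA`.
#'
#' @inheritParams q10_all_pairs
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional RNG seed.
#' @param conf Confidence level of the percentile interval.
#' @return One-row tibble: `q10`, `se` (pairwise, as in [q10_all_pairs()]),
#'   `boot_se`, `ci_low`, `ci_high`, `sensitive`, `n_low`, `n_high`.
#' @export
bootstrap_q10 <- function(replicates_low, replicates_high, t_low, t_high,
                          n_boot = 1000, seed = NULL, conf = 0.95) {
  n_boot <- check_count(n_boot, "n_boot", min = 1L)
  base <- q10_all_pairs(replicates_low, replicates_high, t_low, t_high)
  n_lo <- length(replicates_low)
  n_hi <- length(replicates_high)
  if (n_lo < 2 || n_hi < 2) {
    return(dplyr::mutate(base, boot_se = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, sensitive = NA,
                         n_low = n_lo, n_high = n_hi))
  }
  boots <- with_seed(seed, {
    lo <- matrix(sample(replicates_low, n_lo * n_boot, replace = TRUE),
                 n_lo, n_boot)
    hi <- matrix(sample(replicates_high, n_hi * n_boot, replace = TRUE),
                 n_hi, n_boot)
    q10(colMeans(lo), t_low, colMeans(hi), t_high)
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  dplyr::mutate(base,
    boot_se = sd(boots), ci_low = ci[1], ci_high = ci[2],
    sensitive = ci[1] > 1 || ci[2] < 1,
    n_low = n_lo, n_high = n_hi
  )
}

#' Q10 table for every isolate x substrate x temperature pair
#'
#' Runs [bootstrap_q10()] on QC-passed CUE records for each requested
#' temperature pair within each isolate and substrate.
#'
#' @param records CUE records (e.g. from [qc_filter()]), with columns
#'   `isolate`, `substrate`, `temperature_c`, `cue`.
#' @param pairs List of `c(t_low, t_high)` temperature pairs.
#' @param n_boot,conf Passed to [bootstrap_q10()].
#' @param seed Optional RNG seed (one independent stream per condition).
#' @return Tibble with one row per isolate x substrate x pair.
#' @export
q10_table <- function(records,
                      pairs = list(c(15, 20), c(20, 25), c(15, 25)),
                      n_boot = 1000, seed = NULL, conf = 0.95) {
  stopifnot(all(c("isolate", "substrate", "temperature_c", "cue") %in%
                  names(records)))
  conds <- records |>
    dplyr::distinct(.data$isolate, .data$substrate)
  grid <- tidyr::expand_grid(conds, pair = pairs)
  seeds <- if (is.null(seed)) rep(list(NULL), nrow(grid)) else {
    as.list(derive_seeds(seed, nrow(grid)))
  }
  rows <- purrr::pmap(
    list(grid$isolate, grid$substrate, grid$pair, seeds),
    function(iso, sub, pr, sd_i) {
      lo <- records$cue[records$isolate == iso & records$substrate == sub &
                          records$temperature_c == pr[1]]
      hi <- records$cue[records$isolate == iso & records$substrate == sub &
                          records$temperature_c == pr[2]]
      if (!length(lo) || !length(hi)) return(NULL)
      bootstrap_q10(lo, hi, pr[1], pr[2], n_boot = n_boot,
                    seed = sd_i, conf = conf) |>
        dplyr::mutate(isolate = iso, substrate = sub,
                      t_low = pr[1], t_high = pr[2], .before = 1)
    }
  )
  purrr::list_rbind(purrr::compact(rows))
}
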