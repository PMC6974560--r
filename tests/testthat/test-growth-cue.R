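test_that("window detection finds the exponential run and honours tie-breaks", {
  # 4 flat, 6 exponential (slope 0.3/h), 4 flat points; the flanking points
  # sit off the ramp line on the slope-reducing side, so they are excluded
  tt <- 0:13
  lb <- c(rep(0.5, 4), seq(0.6, 2.1, by = 0.3), rep(2.25, 4))
  w <- find_exponential_window(tt, lb)
  expect_equal(c(w$start, w$end), c(5, 10))
  expect_equal(w$slope, 0.3, tolerance = 1e-12)

  # perfectly log-linear series: longest admissible window wins
  tt8 <- 1:8
  w8 <- find_exponential_window(tt8, 0.2 * tt8)
  expect_equal(c(w8$start, w8$end, w8$n), c(1, 8, 8))

  expect_error(find_exponential_window(1:2, c(0, 1)), "at least")
  expect_error(find_exponential_window(c(1, 1, 2), c(0, 1, 2)), "increasing")
})

test_that("window detection equals the exhaustive lm() oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(5:20, 1)
    tt <- sort(runif(n, 0, 24))
    lb <- cumsum(rnorm(n, 0.1, 0.3))
    w <- find_exponential_window(tt, lb)
    o <- window_oracle(tt, lb)
    expect_equal(c(w$start, w$end), c(o$start, o$end),
                 info = sprintf("case %d", i))
  }
})

test_that("OD converts linearly to biomass carbon", {
  expect_equal(od_to_biomass_c(0, assay_constants()), 0)
  k <- assay_constants(biomass_per_od = 130, culture_ml = 10)
  expect_equal(od_to_biomass_c(0.1, k), 130)
  k1 <- assay_constants(biomass_per_od = 130, culture_ml = 1)
  expect_equal(od_to_biomass_c(1, k1), 130)
  expect_error(od_to_biomass_c(-0.1, k), "negative")
})

test_that("CO2 ppm converts by the ideal gas law with baseline subtraction", {
  k <- assay_constants(headspace_ml = 25)
  expect_equal(co2_to_carbon(c(415, 415), k, 20)[2], 0)
  up <- co2_to_carbon(c(400, 410, 420), k, 20)
  expect_equal(up[3] - up[1], 2 * (up[2] - up[1])) # linear in ppm
  # 22.414 litres at 0 C holds one mole: 1 ppm above baseline = 1 umol CO2
  k_mol <- assay_constants(headspace_ml = 22414)
  got <- co2_to_carbon(c(0, 1), k_mol, 0)[2]
  expect_equal(got, 12.011, tolerance = 1e-3)
})

test_that("exponential rates recover a noiseless curve to 4+ decimals", {
  g <- noiseless_growth(mu = 0.3, cue = 0.6)
  fit <- fit_exponential_rates(g, assay_constants())
  expect_equal(fit$mu, 0.3, tolerance = 1e-6)
  expect_equal(fit$r, 0.2, tolerance = 1e-6)
  expect_equal(fit$cue, 0.6, tolerance = 1e-5)
  expect_lt(fit$mu_p, 1e-10)
  expect_lt(fit$r_p, 1e-10)
})

test_that("constant CO2 gives zero respiration flagged by its F test", {
  g <- noiseless_growth(mu = 0.3, cue = 1)
  fit <- fit_exponential_rates(g, assay_constants())
  expect_equal(fit$r, 0, tolerance = 1e-12)
  expect_gt(fit$r_p, 0.05)
  expect_equal(fit$cue, 1)
})

test_that("cumulative and interval respiration estimators agree when noiseless", {
  g <- noiseless_growth(mu = 0.25, cue = 0.45)
  f1 <- fit_exponential_rates(g, assay_constants(), method = "cumulative")
  f2 <- fit_exponential_rates(g, assay_constants(), method = "interval")
  expect_equal(f1$r, f2$r, tolerance = 0.01)
})

test_that("CUE is the growth fraction of processed carbon", {
  expect_equal(compute_cue(0.2, 0.2), 0.5)
  expect_equal(compute_cue(0.3, 0.1), 0.75)
  expect_equal(compute_cue(0.3, 0), 1)
  expect_error(compute_cue(0, 0.1), "positive")
  expect_error(compute_cue(0.1, -0.1), "non-negative")
})

test_that("CUE is invariant to joint rescaling of carbon units", {
  p <- growth_sim_params(mu_true = 0.3, cue_true = 0.55, od_noise_sd = 0.01,
                         co2_noise_sd = 2, seed = 5)
  g <- simulate_growth_experiment(p, 1)
  base <- fit_exponential_rates(g, assay_constants())
  # rescale biomass carbon by c and respired carbon by c (via headspace):
  # co2_to_carbon is linear in headspace volume
  sc <- 3.7
  k2 <- assay_constants(biomass_per_od = 130 * sc, headspace_ml = 25 * sc)
  scaled <- fit_exponential_rates(g, k2)
  expect_equal(scaled$cue, base$cue, tolerance = 1e-10)
  expect_equal(scaled$mu, base$mu, tolerance = 1e-10)
})

test_that("QC drops failing replicates, then underpowered conditions", {
  rec <- tibble::tibble(
    isolate = "a", substrate = "glc", temperature_c = 15,
    replicate = c("r1", "r2", "r3"),
    mu = 0.3, mu_p = c(0.01, 0.01, 0.01),
    r = 0.1, r_p = c(0.01, 0.2, 0.01), cue = 0.7
  )
  kept <- qc_filter(rec)
  expect_equal(kept$replicate, c("r1", "r3"))

  rec2 <- rec[1:2, ]
  rec2$r_p <- c(0.01, 0.2)
  expect_equal(nrow(qc_filter(rec2)), 0) # whole condition dropped

  expect_equal(nrow(qc_filter(rec |> dplyr::mutate(r_p = 0.01))), 3)
})

test_that("substrate energy density is heat of combustion per carbon", {
  k <- assay_constants(substrate_table = tibble::tibble(
    substrate = c("x2", "x1"), heat_combustion_kj_mol = c(600, 300),
    n_carbon = c(2, 1)
  ))
  expect_equal(energy_per_carbon("x2", k), 300)
  expect_equal(energy_per_carbon("x1", k), 300)
  expect_error(energy_per_carbon("nope", k), "unknown")
  # bundled defaults: glucose is 2805/6
  expect_equal(energy_per_carbon("glucose", assay_constants()), 2805 / 6)
})

test_that("CUE recovery stays accurate under realistic read noise", {
  set.seed(7)
  errs <- replicate(25, {
    mu <- runif(1, 0.1, 0.6)
    cue <- runif(1, 0.3, 0.8)
    p <- growth_sim_params(mu_true = mu, cue_true = cue, od_noise_sd = 0.01,
                           co2_noise_sd = 2, seed = sample.int(1e6, 1))
    est <- estimate_cue(simulate_growth_experiment(p, 1))
    abs(est$cue - cue)
  })
  expect_lt(mean(errs), 0.03)
})
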