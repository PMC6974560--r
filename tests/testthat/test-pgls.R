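make_design <- function(tree, beta = 0.3, lambda_noise = 0.5, seed = 1) {
  n <- length(tree$tip.label)
  set.seed(seed)
  x <- rnorm(n)
  noise <- simulate_trait_bm(tree, sigma2 = 0.1, lambda_sim = lambda_noise,
                             seed = seed + 1)$value
  tibble::tibble(taxon = tree$tip.label, x = x, y = 1 + beta * x + noise)
}

test_that("PGLS with lambda 0 reproduces ordinary least squares exactly", {
  for (s in 1:10) {
    tr <- simulate_tree(sample(10:30, 1), seed = s)
    d <- make_design(tr, seed = 50 + s)
    fit <- pgls_fit(d, y ~ x, tr, lambda = 0)
    ols <- lm(y ~ x, d)
    expect_lt(max(abs(tidy(fit)$estimate - coef(ols))), 1e-10)
    expect_lt(max(abs(tidy(fit)$std.error -
                        summary(ols)$coefficients[, 2])), 1e-10)
  }
})

test_that("intercept-only PGLS returns the GLS phylogenetic mean", {
  tr <- simulate_tree(15, seed = 3)
  tv <- simulate_trait_bm(tr, sigma2 = 0.5, seed = 4)
  d <- dplyr::rename(tv, y = value)[, c("taxon", "y")]
  fit <- pgls_fit(d, y ~ 1, tr, lambda = 1)
  V <- vcv_matrix(tr)
  Vi <- solve(V)
  y <- setNames(d$y, d$taxon)[rownames(V)]
  expect_equal(tidy(fit)$estimate, sum(Vi %*% y) / sum(Vi), tolerance = 1e-10)
})

test_that("fixed-lambda fits agree with nlme gls and corPagel", {
  tr <- simulate_tree(20, seed = 7)
  d <- make_design(tr, seed = 11)
  for (lam in c(0.2, 0.8, 1)) {
    fit <- pgls_fit(d, y ~ x, tr, lambda = lam)
    ref <- nlme::gls(y ~ x, data = as.data.frame(d),
                     correlation = ape::corPagel(lam, tr, form = ~taxon,
                                                 fixed = TRUE),
                     method = "ML")
    expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-8)
    expect_equal(tidy(fit)$std.error,
                 unname(summary(ref)$tTable[, 2]), tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
})

test_that("planted slopes are recovered without bias", {
  slopes <- vapply(1:50, function(s) {
    tr <- simulate_tree(32, seed = 600 + s)
    d <- make_design(tr, beta = 0.05, lambda_noise = 1, seed = 700 + s)
    tidy(pgls_fit(d, y ~ x, tr))$estimate[2]
  }, numeric(1))
  expect_equal(mean(slopes), 0.05, tolerance = 0.2) # mini-run; wide MC margin
})

test_that("degenerate designs are refused with informative errors", {
  tr <- simulate_tree(10, seed = 1)
  d <- make_design(tr, seed = 2)
  expect_error(pgls_fit(d, y ~ x + I(2 * x), tr), "rank-deficient")
  expect_error(pgls_fit(d[1:2, ], y ~ x, tr), "complete cases")
  expect_error(pgls_fit(dplyr::select(d, -x), y ~ x, tr), "missing model")
})

test_that("tidy and glance expose the broom-style summaries", {
  tr <- simulate_tree(12, seed = 9)
  d <- make_design(tr, seed = 10)
  fit <- pgls_fit(d, y ~ x, tr)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$nobs, 12)
  expect_equal(gl$df.residual, 10)
  expect_true(gl$lambda >= 0 && gl$lambda <= 1)
})

test_that("REML profiling is available and shifts only the lambda choice", {
  tr <- simulate_tree(24, seed = 13)
  d <- make_design(tr, lambda_noise = 0.4, seed = 14)
  fml <- pgls_fit(d, y ~ x, tr, lambda = "ML")
  frl <- pgls_fit(d, y ~ x, tr, lambda = "REML")
  expect_gte(frl$lambda, 0)
  # at the same fixed lambda both routes give identical coefficients
  f1 <- pgls_fit(d, y ~ x, tr, lambda = 0.5)
  expect_equal(nrow(tidy(f1)), nrow(tidy(fml)))
  expect_s3_class(frl, "cue_pgls")
})

test_that("residual check passes iid fits and fails omitted phylogenetic structure", {
  tr <- simulate_tree(40, seed = 17)
  set.seed(18)
  # iid world: nothing phylogenetic anywhere
  d0 <- tibble::tibble(taxon = tr$tip.label, x = rnorm(40),
                       y = 0.5 * rnorm(40))
  chk0 <- residual_phylosig_check(pgls_fit(d0, y ~ x, tr, lambda = 0),
                                  n_perm = 499, seed = 1)
  expect_true(chk0$pass)

  # a strongly phylogenetic covariate omitted from the model, with lambda
  # forced to 0 so the fitted covariance cannot absorb it
  z <- simulate_trait_bm(tr, sigma2 = 4, seed = 19)$value
  d1 <- tibble::tibble(taxon = tr$tip.label, x = rnorm(40),
                       y = z + 0.05 * rnorm(40))
  chk1 <- residual_phylosig_check(pgls_fit(d1, y ~ x, tr, lambda = 0),
                                  n_perm = 499, seed = 2)
  expect_false(chk1$pass)

  # constant residuals degenerate to a warned pass
  d2 <- tibble::tibble(taxon = tr$tip.label, x = seq_len(40), y = 2 * seq_len(40))
  fit2 <- pgls_fit(d2, y ~ x, tr, lambda = 0)
  expect_warning(chk2 <- residual_phylosig_check(fit2, n_perm = 99), "constant")
  expect_true(chk2$pass)
})

test_that("screen and pgls_fit agree at a shared fixed lambda", {
  tr <- simulate_tree(18, seed = 23)
  g <- simulate_genomes(tr, n_kos = 12, n_causal = 0, seed = 24)
  dens <- standardize_density(g$features)
  cache <- cuephylo:::phylo_cache(tr)
  y <- setNames(g$cue$value, g$cue$taxon)[cache$labels]
  X <- cuephylo:::feature_matrix(dens, cache$labels)
  scr <- cuephylo:::pgls_screen(cache, y, X)
  for (f in colnames(X)[1:4]) {
    d <- tibble::tibble(taxon = dens$taxon, cue = unname(y[dens$taxon]),
                        x = dens[[f]])
    co <- tidy(pgls_fit(d, cue ~ x, tr, lambda = scr$lambda[scr$feature == f]))
    expect_equal(scr$slope[scr$feature == f], co$estimate[2], tolerance = 1e-8)
    expect_equal(scr$p[scr$feature == f], co$p.value[2], tolerance = 1e-8)
  }
})
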