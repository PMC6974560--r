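test_that("tree covariance matches hand-computed path sums and ape", {
  V <- vcv_matrix(balanced_tree4())
  expect_equal(unname(V["a", "a"]), 3)
  expect_equal(unname(V["a", "b"]), 2)
  expect_equal(unname(V["a", "c"]), 0)
  expect_equal(unname(V["c", "d"]), 1)

  Vs <- vcv_matrix(star_tree4())
  expect_equal(unname(Vs), diag(4))

  for (s in 1:5) {
    tr <- simulate_tree(sample(5:40, 1), seed = s)
    V1 <- vcv_matrix(tr)
    V2 <- ape::vcv(tr)[rownames(V1), colnames(V1)]
    expect_equal(V1, V2, tolerance = 1e-12)
  }
})

test_that("lambda transform rescales only the off-diagonal", {
  V <- vcv_matrix(balanced_tree4())
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(diag(V)),
               ignore_attr = TRUE)
  half <- lambda_transform(V, 0.5)
  expect_equal(unname(half["a", "b"]), 1)
  expect_equal(diag(half), diag(V))
  expect_error(lambda_transform(V, -0.1), "lambda")
})

test_that("patristic distances are additive path lengths", {
  D <- patristic_distances(balanced_tree4())
  expect_equal(unname(D["a", "b"]), 2)
  expect_equal(unname(D["a", "c"]), 6)
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
})

test_that("Blomberg's K is 1 on a star tree and matches phytools elsewhere", {
  y <- c(a = 0.3, b = 0.9, c = 0.1, d = 0.5)
  expect_equal(blomberg_k(star_tree4(), y), 1, tolerance = 1e-10)
  expect_error(blomberg_k(star_tree4(), c(a = 1, b = 1, c = 1, d = 1)),
               "variance")

  set.seed(10)
  for (s in 1:10) {
    n <- sample(5:8, 1)
    tr <- simulate_tree(n, seed = 100 + s)
    tv <- simulate_trait_bm(tr, sigma2 = 0.3, seed = 200 + s)
    y <- setNames(tv$value, tv$taxon)
    expect_equal(blomberg_k(tr, y),
                 as.numeric(phytools::phylosig(tr, y, method = "K")),
                 tolerance = 1e-8, info = sprintf("tree %d", s))
  }
})

test_that("K permutation p is reproducible and detects clustered traits", {
  tr <- two_clade_tree(5)
  y <- setNames(c(rnorm(5, 0, 0.05), rnorm(5, 2, 0.05)), tr$tip.label)
  p1 <- blomberg_k_pvalue(tr, y, n_perm = 999, seed = 1)
  p2 <- blomberg_k_pvalue(tr, y, n_perm = 999, seed = 1)
  expect_identical(p1, p2)
  expect_lte(p1$p, 0.05)

  # white noise on the same tree: p should not be systematically small
  set.seed(2)
  ps <- replicate(40, {
    yn <- setNames(rnorm(10), tr$tip.label)
    blomberg_k_pvalue(tr, yn, n_perm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("Pagel's lambda ML matches phytools on simulated traits", {
  for (s in 1:6) {
    tr <- simulate_tree(24, seed = 300 + s)
    tv <- simulate_trait_bm(tr, sigma2 = 0.4,
                            lambda_sim = c(0, 0.5, 1)[1 + s %% 3],
                            seed = 400 + s)
    y <- setNames(tv$value, tv$taxon)
    ours <- pagel_lambda_ml(tr, y)
    ref <- phytools::phylosig(tr, y, method = "lambda")
    if (ref$lambda <= 1) {
      expect_equal(ours$lambda, ref$lambda, tolerance = 1e-2)
      expect_equal(ours$loglik, ref$logL, tolerance = 1e-3)
    } else {
      # phytools searches slightly past 1; this implementation caps at 1
      expect_equal(ours$lambda, 1, tolerance = 1e-8)
      expect_lte(ours$loglik, ref$logL + 1e-6)
    }
  }
})

test_that("lambda log-likelihood agrees with an independent dense-matrix route", {
  tr <- simulate_tree(16, seed = 5)
  tv <- simulate_trait_bm(tr, sigma2 = 0.2, seed = 6)
  y <- setNames(tv$value, tv$taxon)
  for (lam in c(0, 0.4, 1)) {
    V <- lambda_transform(vcv_matrix(tr)[names(y), names(y)], lam)
    n <- length(y)
    Vi <- solve(V)
    mu <- sum(Vi %*% y) / sum(Vi)
    r <- y - mu
    s2 <- drop(crossprod(r, Vi %*% r)) / n
    ll_dense <- -0.5 * (n * log(2 * pi * s2) +
                          as.numeric(determinant(V)$modulus) + n)
    model <- cuephylo:::lambda_model(cuephylo:::phylo_cache(tr), y,
                                     matrix(1, n, 1))
    ll_fast <- cuephylo:::lambda_model_eval(model, lam)$loglik
    expect_equal(ll_fast, ll_dense, tolerance = 1e-8)
  }
})

test_that("boundary lambda estimates give a unit LRT p", {
  tr <- simulate_tree(32, seed = 8)
  set.seed(9)
  y <- setNames(rnorm(32), tr$tip.label) # no signal: lambda-hat ~ 0
  res <- pagel_lambda_ml(tr, y)
  if (res$lambda <= 1e-10) expect_equal(res$p, 1)
  expect_gte(res$p, 0)
})

test_that("Brownian reference intervals bracket K = 1 and reach lambda = 1", {
  tr <- simulate_tree(16, seed = 12)
  ci <- bm_signal_ci(tr, n_sim = 300, seed = 4)
  k_row <- ci[ci$statistic == "k", ]
  l_row <- ci[ci$statistic == "lambda", ]
  expect_lt(k_row$lower, 1)
  expect_gt(k_row$upper, 1)
  expect_equal(l_row$upper, 1, tolerance = 1e-6) # boundary pile-up under BM
  expect_identical(ci, bm_signal_ci(tr, n_sim = 300, seed = 4))
  expect_warning(bm_signal_ci(tr, n_sim = 50, seed = 1), "unstable")
})

test_that("phylo_signal combines both statistics into one tidy row", {
  tr <- simulate_tree(12, seed = 21)
  tv <- simulate_trait_bm(tr, sigma2 = 0.3, seed = 22)
  row <- phylo_signal(tr, tv, n_perm = 199, seed = 1)
  expect_equal(nrow(row), 1)
  expect_named(row, c("n", "k", "k_p", "lambda", "lambda_logl", "lambda_p"))
  expect_true(row$k > 0 && row$lambda >= 0 && row$lambda <= 1)
})
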