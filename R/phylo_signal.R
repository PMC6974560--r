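#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the observed ratio of the tip-level mean squared error around
#' the GLS phylogenetic mean (`MSE0`) to the phylogenetically corrected mean
#' squared error (`MSE`, weighted by the inverse Brownian covariance), against
#' the value of that ratio expected under Brownian motion,
#' `(tr(V) - n / sum(V^-1)) / (n - 1)`. K = 1 is the Brownian expectation;
#' K < 1 indicates less similarity among relatives than Brownian motion
#' predicts, K > 1 more.
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param trait Named numeric vector or (taxon, value) tibble covering every
#'   tip.
#' @return The scalar K.
#' @export
blomberg_k <- function(tree, trait) {
  y <- as_trait_vector(trait, tree)
  if (var(y) <= 0) abort_bad_arg("trait has zero variance; K undefined.")
  V <- vcv_matrix(tree)
  k_from_v(y, V)
}

# core K computation given trait (tree tip order) and covariance
k_from_v <- function(y, V) {
  n <- length(y)
  Vinv <- solve(V)
  one <- rep(1, n)
  sum_vinv <- sum(Vinv)
  a <- sum(Vinv %*% y) / sum_vinv
  r <- y - a
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(crossprod(r, Vinv %*% r)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum_vinv) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for Blomberg's K
#'
#' Shuffles tip labels and compares the phylogenetically weighted mean squared
#' error of the observed arrangement to its permutation distribution: traits
#' with phylogenetic signal have a lower weighted MSE than random
#' arrangements. One-sided with add-one smoothing,
#' `p = (1 + #\{MSE_perm <= MSE_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams blomberg_k
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed.
#' @return A list with `k`, `p`, and `n_perm`.
#' @export
blomberg_k_pvalue <- function(tree, trait, n_perm = 999, seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  y <- as_trait_vector(trait, tree)
  if (var(y) <= 0) abort_bad_arg("trait has zero variance; K undefined.")
  V <- vcv_matrix(tree)
  n <- length(y)
  Vinv <- solve(V)
  cvec <- colSums(Vinv) / sum(Vinv) # GLS mean weights

  mse_of <- function(Y) {
    # Y: n x m matrix of trait arrangements (columns)
    A <- drop(crossprod(cvec, Y))
    R <- Y - rep(1, n) %o% A
    colSums(R * (Vinv %*% R))
  }
  obs <- mse_of(matrix(y, ncol = 1))
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  })
  perm_mse <- mse_of(matrix(y[perms], nrow = n))
  list(
    k = k_from_v(y, V),
    p = (1 + sum(perm_mse <= obs)) / (n_perm + 1),
    n_perm = n_perm
  )
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Maximises the multivariate-normal log likelihood of the trait with
#' covariance `sigma2 * V_lambda` over lambda in `[0, lambda_max]`, profiling
#' the mean and `sigma2` out analytically. Significance is a likelihood-ratio
#' test against `lambda = 0` referred to a chi-squared distribution with one
#' degree of freedom (the convention of the common comparative-methods
#' implementations; anticonservative at the boundary).
#'
#' @inheritParams blomberg_k
#' @param lambda_max Upper bound of the search; 1 for ultrametric trees.
#' @return A list: `lambda`, `loglik`, `loglik0` (at lambda = 0), `lrt_stat`,
#'   `p`, `sigma2`, and the GLS mean `mu`.
#' @export
pagel_lambda_ml <- function(tree, trait, lambda_max = 1) {
  y <- as_trait_vector(trait, tree)
  if (var(y) <= 0) abort_bad_arg("trait has zero variance; lambda undefined.")
  cache <- phylo_cache(tree)
  lambda_ml_cached(cache, y, lambda_max = lambda_max)
}

lambda_ml_cached <- function(cache, y, lambda_max = 1) {
  model <- lambda_model(cache, y, matrix(1, length(y), 1))
  best <- lambda_model_ml(model, lambda_max = lambda_max)
  ev0 <- lambda_model_eval(model, 0)
  stat <- max(0, 2 * (best$loglik - ev0$loglik))
  p <- if (best$lambda <= 1e-10 || stat <= 0) 1 else pchisq(stat, 1, lower.tail = FALSE)
  list(
    lambda = best$lambda, loglik = best$loglik, loglik0 = ev0$loglik,
    lrt_stat = stat, p = p, sigma2 = best$sigma2_ml, mu = unname(best$beta[1])
  )
}

#' Combined phylogenetic-signal summary for one trait
#'
#' Blomberg's K with its permutation p value and Pagel's lambda with its
#' likelihood-ratio p value, as one tidy row (the layout of a signal table
#' with one row per substrate x temperature condition).
#'
#' @inheritParams blomberg_k_pvalue
#' @return A one-row tibble: `n`, `k`, `k_p`, `lambda`, `lambda_logl`,
#'   `lambda_p`.
#' @export
phylo_signal <- function(tree, trait, n_perm = 999, seed = NULL) {
  kp <- blomberg_k_pvalue(tree, trait, n_perm = n_perm, seed = seed)
  lam <- pagel_lambda_ml(tree, trait)
  tibble(
    n = length(as_trait_vector(trait, tree)),
    k = kp$k, k_p = kp$p,
    lambda = lam$lambda, lambda_logl = lam$loglik, lambda_p = lam$p
  )
}

#' Brownian-motion reference intervals for K and lambda
#'
#' Simulates Brownian traits on the fixed tree and returns the 2.5% and 97.5%
#' quantiles of Blomberg's K and of the ML lambda estimate, i.e. the interval
#' within which these statistics fall for a trait that truly evolved by
#' Brownian motion on this tree.
#'
#' @inheritParams blomberg_k
#' @param n_sim Number of Brownian simulations (values below 100 warn).
#' @param seed Optional RNG seed.
#' @return A tibble with one row per statistic (`k`, `lambda`): `lower`,
#'   `upper`, `median`.
#' @export
bm_signal_ci <- function(tree, n_sim = 1000, seed = NULL) {
  n_sim <- check_count(n_sim, "n_sim", min = 1L)
  if (n_sim < 100) warning("n_sim < 100 gives unstable interval estimates.")
  cache <- phylo_cache(tree)
  V <- cache$V
  n <- nrow(V)
  L <- t(chol(V))
  Y <- with_seed(seed, L %*% matrix(rnorm(n * n_sim), n, n_sim))

  Vinv <- solve(V)
  cvec <- colSums(Vinv) / sum(Vinv)
  expected <- (sum(diag(V)) - n / sum(Vinv)) / (n - 1)
  A <- drop(crossprod(cvec, Y))
  R <- Y - rep(1, n) %o% A
  mse0 <- colSums(R^2) / (n - 1)
  mse <- colSums(R * (Vinv %*% R)) / (n - 1)
  k_sims <- (mse0 / mse) / expected

  lambda_sims <- vapply(seq_len(n_sim), function(i) {
    lambda_ml_cached(cache, setNames(Y[, i], cache$labels))$lambda
  }, numeric(1))

  tibble(
    statistic = c("k", "lambda"),
    lower = c(quantile(k_sims, 0.025, names = FALSE),
              quantile(lambda_sims, 0.025, names = FALSE)),
    median = c(median(k_sims), median(lambda_sims)),
    upper = c(quantile(k_sims, 0.975, names = FALSE),
              quantile(lambda_sims, 0.975, names = FALSE)),
    n_sim = n_sim
  )
}
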