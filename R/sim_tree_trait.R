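#' Simulate an ultrametric phylogeny
#'
#' Draws a rooted, binary, ultrametric tree under a Yule (pure-birth) or
#' constant-rate birth-death process, as a stand-in for an inferred isolate
#' phylogeny.
#'
#' @param n_tips Number of tips (at least 3).
#' @param model `"yule"` or `"birth-death"`.
#' @param birth_rate,death_rate Speciation and extinction rates; the death
#'   rate must be strictly smaller than the birth rate (and is forced to 0
#'   under `"yule"`).
#' @param seed Optional RNG seed.
#' @param tip_prefix Prefix for tip labels (`t1`, `t2`, ...).
#' @return An `ape::phylo` tree with `n_tips` labelled tips.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "birth-death"),
                          birth_rate = 1, death_rate = 0, seed = NULL,
                          tip_prefix = "t") {
  n_tips <- check_count(n_tips, "n_tips", min = 3L)
  model <- match.arg(model)
  check_number(birth_rate, "birth_rate", min = 0, allow_min = FALSE)
  if (model == "yule") death_rate <- 0
  check_number(death_rate, "death_rate", min = 0)
  if (death_rate >= birth_rate) {
    abort_bad_arg("`death_rate` must be strictly smaller than `birth_rate`.")
  }
  tree <- with_seed(seed, {
    ape::rphylo(n_tips, birth = birth_rate, death = death_rate)
  })
  tree$tip.label <- paste0(tip_prefix, seq_len(n_tips))
  tree
}

#' Simulate a trait under lambda-transformed Brownian motion
#'
#' Draws tip values from a multivariate normal with mean `root_value` and
#' covariance `sigma2 * V_lambda`, where `V` is the tree's Brownian covariance
#' and `V_lambda` its Pagel transform (off-diagonals scaled by `lambda_sim`).
#' `lambda_sim = 1` is plain Brownian motion; `lambda_sim = 0` gives mutually
#' independent tips.
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param lambda_sim Pagel transform in `[0, 1]`.
#' @param root_value Trait value at the root (the mean).
#' @param n Number of independent draws.
#' @param seed Optional RNG seed.
#' @return A tibble with columns `taxon`, `draw`, `value`.
#' @export
simulate_trait_bm <- function(tree, sigma2 = 1, lambda_sim = 1,
                              root_value = 0, n = 1, seed = NULL) {
  check_number(sigma2, "sigma2", min = 0)
  check_number(lambda_sim, "lambda_sim", min = 0, max = 1)
  n <- check_count(n, "n", min = 1L)
  if (length(tree$tip.label) < 3) abort_bad_arg("tree must have at least 3 tips.")
  n_tip <- length(tree$tip.label)
  if (sigma2 == 0) {
    vals <- matrix(root_value, n_tip, n)
  } else {
    V <- vcv_matrix(tree)
    Vl <- V * lambda_sim
    diag(Vl) <- diag(V)
    L <- t(chol(sigma2 * Vl))
    vals <- with_seed(seed, root_value + L %*% matrix(rnorm(n_tip * n), n_tip, n))
  }
  tibble(
    taxon = rep(tree$tip.label, times = n),
    draw = rep(seq_len(n), each = n_tip),
    value = as.vector(vals)
  )
}
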