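# Dense-matrix machinery shared by the phylogenetic comparative statistics.
#
# The Brownian-motion covariance of a rooted tree has V[i, j] equal to the
# shared root-to-MRCA branch length of tips i and j. Pagel's lambda rescales
# the off-diagonal entries only. For ultrametric trees V_lambda =
# lambda * V + (1 - lambda) * depth * I shares V's eigenvectors, so one
# eigendecomposition per tree makes every lambda likelihood evaluation O(n)
# after rotating the data once; non-ultrametric trees fall back to a Cholesky
# factorisation per evaluation.

#' Brownian-motion covariance matrix of a tree
#'
#' `V[i, j]` is the branch length shared by tips i and j (root to their most
#' recent common ancestor); `V[i, i]` is the root-to-tip distance.
#'
#' @param tree A rooted `ape::phylo` tree with branch lengths.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
vcv_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) abort_bad_arg("`tree` must be an ape phylo object.")
  if (is.null(tree$edge.length)) abort_bad_arg("tree has no branch lengths.")
  if (any(tree$edge.length < 0)) abort_bad_arg("negative branch lengths.")
  n <- length(tree$tip.label)
  n_node <- tree$Nnode

  cw <- stats::reorder(tree, "cladewise")
  depth <- numeric(n + n_node)
  for (k in seq_len(nrow(cw$edge))) {
    depth[cw$edge[k, 2]] <- depth[cw$edge[k, 1]] + cw$edge.length[k]
  }

  po <- stats::reorder(tree, "postorder")
  tipsets <- c(as.list(seq_len(n)), vector("list", n_node))
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n)]
  children <- split(po$edge[, 2], po$edge[, 1])
  # postorder over internal nodes: each tip pair is assigned once, by its MRCA
  for (nd in unique(po$edge[, 1])) {
    chs <- children[[as.character(nd)]]
    acc <- tipsets[[chs[1]]]
    if (length(chs) > 1) {
      for (j in 2:length(chs)) {
        tj <- tipsets[[chs[j]]]
        V[acc, tj] <- depth[nd]
        V[tj, acc] <- depth[nd]
        acc <- c(acc, tj)
      }
    }
    tipsets[[nd]] <- acc
  }
  V
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of `V` by `lambda`, leaving the
#' diagonal unchanged. `lambda = 1` returns `V`; `lambda = 0` removes all
#' phylogenetic covariance.
#'
#' @param V Covariance matrix (from [vcv_matrix()]).
#' @param lambda Scalar in `[0, lambda_max]`; the result must stay positive
#'   definite.
#' @return The transformed matrix.
#' @export
lambda_transform <- function(V, lambda) {
  check_number(lambda, "lambda", min = 0)
  Vl <- V * lambda
  diag(Vl) <- diag(V)
  ch <- tryCatch(chol(Vl), error = function(e) NULL)
  if (is.null(ch)) abort_bad_arg("lambda transform is not positive definite.")
  Vl
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between each pair of tips, computed
#' from the Brownian covariance as `V[i,i] + V[j,j] - 2 V[i,j]`.
#'
#' @inheritParams vcv_matrix
#' @return A symmetric distance matrix.
#' @export
patristic_distances <- function(tree) {
  V <- vcv_matrix(tree)
  outer(diag(V), diag(V), "+") - 2 * V
}

# Cached spectral representation of a tree's covariance.
phylo_cache <- function(tree, V = NULL) {
  V <- V %||% vcv_matrix(tree)
  depth <- diag(V)
  T_depth <- max(depth)
  ultra <- all(abs(depth - T_depth) < 1e-8 * max(T_depth, 1))
  cache <- list(V = V, n = nrow(V), labels = rownames(V),
                T = T_depth, ultra = ultra)
  if (ultra) {
    eig <- eigen(V, symmetric = TRUE)
    cache$U <- eig$vectors
    cache$d <- pmax(eig$values, 0)
  }
  cache
}

# Rotated regression model for profile-lambda likelihood evaluation.
# X and y are in tip order of cache$labels.
lambda_model <- function(cache, y, X) {
  if (cache$ultra) {
    list(
      ultra = TRUE, n = cache$n, p = ncol(X),
      d = cache$d, T = cache$T,
      yt = drop(crossprod(cache$U, y)),
      Xt = crossprod(cache$U, X)
    )
  } else {
    list(ultra = FALSE, n = cache$n, p = ncol(X), V = cache$V, y = y, X = X)
  }
}

# GLS fit at a fixed lambda. Returns the profile log-likelihood (sigma2
# profiled out; `criterion = "reml"` adds the REML adjustment terms),
# coefficients, and the pieces needed for t tests.
lambda_model_eval <- function(model, lambda, criterion = c("ml", "reml")) {
  criterion <- match.arg(criterion)
  n <- model$n
  if (model$ultra) {
    w <- lambda * model$d + (1 - lambda) * model$T
    if (any(w <= 1e-12)) return(NULL)
    yt <- model$yt
    Xt <- model$Xt
    logdet <- sum(log(w))
  } else {
    Vl <- model$V * lambda
    diag(Vl) <- diag(model$V)
    R <- tryCatch(chol(Vl), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    yt <- backsolve(R, model$y, transpose = TRUE)
    Xt <- backsolve(R, model$X, transpose = TRUE)
    w <- rep(1, n)
    logdet <- 2 * sum(log(diag(R)))
  }
  WX <- Xt / w
  XtWX <- crossprod(Xt, WX)
  XtWy <- crossprod(WX, yt)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  resid_t <- yt - Xt %*% beta
  rss <- sum(resid_t^2 / w)
  sigma2_ml <- rss / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdet + n)
  p <- ncol(model$Xt %||% model$X)
  reml <- -0.5 * ((n - p) * log(2 * pi * rss / (n - p)) + logdet +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
  list(
    lambda = lambda, beta = drop(beta), rss = rss, sigma2_ml = sigma2_ml,
    loglik = loglik, criterion = if (criterion == "ml") loglik else as.numeric(reml),
    XtWX = XtWX
  )
}

# Profile estimate of lambda on [0, lambda_max] by ML or REML:
# coarse grid to dodge local optima, then bounded scalar refinement.
lambda_model_ml <- function(model, lambda_max = 1, tol = 1e-8,
                            grid = seq(0, 1, by = 0.1),
                            criterion = c("ml", "reml")) {
  criterion <- match.arg(criterion)
  crit_of <- function(l) {
    ev <- lambda_model_eval(model, l, criterion = criterion)
    if (is.null(ev)) -Inf else ev$criterion
  }
  grid <- unique(pmin(grid, lambda_max))
  lls <- vapply(grid, crit_of, numeric(1))
  if (all(!is.finite(lls))) abort_bad_arg("lambda likelihood undefined on the whole grid.")
  i <- which.max(lls)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  if (hi > lo) {
    opt <- optimize(crit_of, interval = c(lo, hi), maximum = TRUE, tol = tol)
    # keep whichever of {grid best, refined} is better, and snap to the
    # boundary when it wins
    cand <- c(grid[i], opt$maximum, lo, hi)
  } else {
    cand <- grid[i]
  }
  evs <- lapply(cand, lambda_model_eval, model = model, criterion = criterion)
  ll <- vapply(evs, function(e) if (is.null(e)) -Inf else e$criterion, numeric(1))
  evs[[which.max(ll)]]
}
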