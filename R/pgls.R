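#' Phylogenetic generalized least squares with profiled lambda
#'
#' Fits a linear model whose residual covariance is `sigma2 * V_lambda`, the
#' lambda-transformed Brownian covariance of the tree. By default lambda is
#' estimated by maximum likelihood jointly with the coefficients (profiling
#' the coefficients and `sigma2` analytically), which lets the model absorb
#' anything from no phylogenetic residual structure (`lambda = 0`, ordinary
#' least squares) to full Brownian structure (`lambda = 1`). Coefficient
#' standard errors use the unbiased residual variance with `n - p` degrees of
#' freedom.
#'
#' @param data Data frame with a `taxon` column matching tree tip labels plus
#'   the model variables. Incomplete rows are dropped.
#' @param formula Model formula, e.g. `cue ~ rrn`.
#' @param tree A rooted `ape::phylo` tree covering all taxa in `data`.
#' @param lambda `"ML"` (default, profile maximum likelihood), `"REML"`
#'   (restricted likelihood for the lambda profile, which reduces the
#'   small-sample downward bias of the lambda estimate), or a fixed value in
#'   `[0, 1]`.
#' @return An object of class `cue_pgls`; see [tidy.cue_pgls()] and
#'   [glance.cue_pgls()].
#' @export
#' @examples
#' tree <- simulate_tree(12, seed = 1)
#' tr <- simulate_trait_bm(tree, sigma2 = 0.1, seed = 2)
#' d <- dplyr::mutate(tr, cue = value + 0.1, x = rnorm(12))
#' fit <- pgls_fit(d, cue ~ x, tree)
#' tidy(fit)
pgls_fit <- function(data, formula, tree, lambda = "ML") {
  if (!"taxon" %in% names(data)) abort_bad_arg("`data` needs a `taxon` column.")
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    abort_bad_arg(paste0("missing model variables: ",
                         paste(missing_vars, collapse = ", ")))
  }
  data <- data[complete.cases(data[, c("taxon", vars), drop = FALSE]), ]
  data <- data[data$taxon %in% tree$tip.label, ]
  if (anyDuplicated(data$taxon)) abort_bad_arg("duplicated taxa in `data`.")
  keep <- tree$tip.label[tree$tip.label %in% data$taxon]
  sub_tree <- if (length(keep) < length(tree$tip.label)) {
    ape::keep.tip(tree, keep)
  } else tree
  data <- data[match(sub_tree$tip.label, data$taxon), ]

  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) abort_bad_arg("need at least p + 2 complete cases for PGLS.")
  if (qr(X)$rank < p) abort_bad_arg("rank-deficient design matrix.")

  cache <- phylo_cache(sub_tree)
  model <- lambda_model(cache, y, X)
  fit <- if (identical(lambda, "ML") || identical(lambda, "REML")) {
    lambda_model_ml(model, criterion = tolower(lambda))
  } else {
    check_number(lambda, "lambda", min = 0, max = 1)
    ev <- lambda_model_eval(model, lambda)
    if (is.null(ev)) abort_bad_arg("PGLS fit failed at the supplied lambda.")
    ev
  }

  df_resid <- n - p
  sigma2_hat <- fit$rss / df_resid
  cov_beta <- sigma2_hat * solve(fit$XtWX)
  se <- sqrt(diag(cov_beta))
  tval <- fit$beta / se
  pval <- 2 * pt(-abs(tval), df = df_resid)
  fitted <- drop(X %*% fit$beta)

  structure(
    list(
      coefficients = tibble(
        term = colnames(X), estimate = unname(fit$beta),
        std.error = unname(se), statistic = unname(tval),
        p.value = unname(pval)
      ),
      lambda = fit$lambda, loglik = fit$loglik,
      sigma2 = sigma2_hat, n = n, df.residual = df_resid,
      residuals = setNames(y - fitted, data$taxon),
      residuals_normalized = normalized_residuals(cache, fit$lambda,
                                                  y - fitted, data$taxon),
      fitted = setNames(fitted, data$taxon),
      formula = formula, tree = sub_tree,
      lambda_mode = if (is.character(lambda)) lambda else "fixed"
    ),
    class = "cue_pgls"
  )
}

#' @export
print.cue_pgls <- function(x, ...) {
  cat("Phylogenetic GLS:", deparse(x$formula), "\n")
  cat(sprintf("n = %d, lambda (%s) = %.4f, logLik = %.3f\n",
              x$n, x$lambda_mode, x$lambda, x$loglik))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a PGLS fit
#'
#' @param x A `cue_pgls` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
tidy.cue_pgls <- function(x, ...) x$coefficients

#' One-row summary of a PGLS fit
#'
#' @inheritParams tidy.cue_pgls
#' @return Tibble: `lambda`, `logLik`, `sigma2`, `nobs`, `df.residual`.
#' @export
glance.cue_pgls <- function(x, ...) {
  tibble(
    lambda = x$lambda, logLik = x$loglik, sigma2 = x$sigma2,
    nobs = x$n, df.residual = x$df.residual
  )
}

# whiten response residuals by the fitted covariance: under a correctly
# specified model these are iid, which is what the residual-signal check
# should find
normalized_residuals <- function(cache, lambda, resid, taxa) {
  Vl <- cache$V * lambda
  diag(Vl) <- diag(cache$V)
  R <- chol(Vl)
  setNames(drop(backsolve(R, resid, transpose = TRUE)), taxa)
}

#' Residuals of a PGLS fit
#'
#' @param object A `cue_pgls` fit.
#' @param type `"response"` (observed minus fitted) or `"normalized"`
#'   (whitened by the fitted lambda covariance; iid under a correctly
#'   specified model).
#' @param ... Unused.
#' @export
residuals.cue_pgls <- function(object, type = c("response", "normalized"),
                               ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$residuals_normalized
}

#' @export
fitted.cue_pgls <- function(object, ...) object$fitted

#' Check a PGLS fit's residuals for leftover phylogenetic signal
#'
#' Computes Blomberg's K (permutation test) and Pagel's lambda (likelihood
#' ratio test) on the model residuals and passes when neither is significant
#' at `alpha`. The check's question is whether the fitted covariance removed
#' the phylogenetic structure, so it defaults to the normalized
#' (phylogeny-corrected) residuals: response-scale residuals of any model
#' with a positive fitted lambda retain structure by construction. Constant
#' residuals are degenerate and reported as a pass with a warning.
#'
#' @param fit A `cue_pgls` object.
#' @param n_perm Permutations for the K test.
#' @param seed Optional RNG seed.
#' @param alpha Significance level.
#' @param type Residual type, `"normalized"` (default) or `"response"`.
#' @return One-row tibble: `k`, `k_p`, `lambda`, `lambda_p`, `pass`.
#' @export
residual_phylosig_check <- function(fit, n_perm = 999, seed = NULL,
                                    alpha = 0.05,
                                    type = c("normalized", "response")) {
  r <- residuals(fit, type = match.arg(type))
  if (var(r) <= 1e-20 * max(1, mean(r)^2)) {
    warning("residuals are (near-)constant; phylogenetic-signal check degenerate.")
    return(tibble(k = NA_real_, k_p = NA_real_, lambda = NA_real_,
                  lambda_p = NA_real_, pass = TRUE))
  }
  kp <- blomberg_k_pvalue(fit$tree, r, n_perm = n_perm, seed = seed)
  lam <- pagel_lambda_ml(fit$tree, r)
  tibble(
    k = kp$k, k_p = kp$p, lambda = lam$lambda, lambda_p = lam$p,
    pass = kp$p > alpha && lam$p > alpha
  )
}

# Vectorised single-predictor PGLS screen used by the marker pipeline.
#
# For each column of `features`, fits response ~ feature with lambda profiled
# on a fixed grid (the grid resolution is the documented tolerance of the
# screen's lambda estimation step). All features share the per-lambda
# whitening, so the whole screen is a handful of matrix products per lambda
# value. The default profile criterion is REML, which at screen-sized n
# removes most of the downward bias of the lambda estimate (and with it most
# of the false-positive inflation of the slope test); "ml" reproduces the
# plain profile-likelihood behaviour.
#
# cache: phylo_cache of the (sub)tree; y: response in cache label order;
# features: numeric matrix, rows in cache label order.
pgls_screen <- function(cache, y, features,
                        lambda_grid = seq(0, 1, by = 0.05),
                        criterion = c("reml", "ml")) {
  criterion <- match.arg(criterion)
  n <- length(y)
  m <- ncol(features)
  if (cache$ultra) {
    yt <- drop(crossprod(cache$U, y))
    Ft <- crossprod(cache$U, features)
    onet <- drop(crossprod(cache$U, rep(1, n)))
  }
  best_ll <- rep(-Inf, m)
  out <- list(lambda = rep(NA_real_, m), slope = rep(NA_real_, m),
              se = rep(NA_real_, m), t = rep(NA_real_, m),
              p = rep(NA_real_, m))
  for (lam in lambda_grid) {
    if (cache$ultra) {
      w <- lam * cache$d + (1 - lam) * cache$T
      if (any(w <= 1e-12)) next
      v <- 1 / w
      logdet <- sum(log(w))
      yt_l <- yt; Ft_l <- Ft; onet_l <- onet
    } else {
      Vl <- cache$V * lam
      diag(Vl) <- diag(cache$V)
      R <- tryCatch(chol(Vl), error = function(e) NULL)
      if (is.null(R)) next
      yt_l <- backsolve(R, y, transpose = TRUE)
      Ft_l <- backsolve(R, features, transpose = TRUE)
      onet_l <- backsolve(R, rep(1, n), transpose = TRUE)
      v <- rep(1, n)
      logdet <- 2 * sum(log(diag(R)))
    }
    s0 <- sum(v * onet_l^2)
    sy <- sum(v * onet_l * yt_l)
    syy <- sum(v * yt_l^2)
    sx <- colSums(v * onet_l * Ft_l)
    sxx <- colSums(v * Ft_l^2)
    sxy <- colSums(v * Ft_l * yt_l)
    denom <- s0 * sxx - sx^2
    ok <- denom > 1e-12 * pmax(1, s0 * sxx)
    slope <- ifelse(ok, (s0 * sxy - sx * sy) / denom, NA_real_)
    intercept <- (sy - slope * sx) / s0
    rss <- pmax(syy - intercept * sy - slope * sxy, 1e-300)
    ll <- if (criterion == "ml") {
      -0.5 * (n * log(2 * pi * rss / n) + logdet + n)
    } else {
      -0.5 * ((n - 2) * log(2 * pi * rss / (n - 2)) + logdet + log(denom) +
                (n - 2))
    }
    ll[!ok] <- -Inf
    upd <- ll > best_ll
    if (any(upd)) {
      se <- sqrt((rss / (n - 2)) * s0 / denom)
      tval <- slope / se
      best_ll[upd] <- ll[upd]
      out$lambda[upd] <- lam
      out$slope[upd] <- slope[upd]
      out$se[upd] <- se[upd]
      out$t[upd] <- tval[upd]
      out$p[upd] <- (2 * pt(-abs(tval), df = n - 2))[upd]
    }
  }
  tibble(
    feature = colnames(features) %||% as.character(seq_len(m)),
    lambda = out$lambda, slope = out$slope, se = out$se,
    statistic = out$t, p = out$p, loglik = best_ll
  )
}
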