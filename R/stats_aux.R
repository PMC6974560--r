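#' Repeated-measures correlation
#'
#' The common within-subject association between two repeatedly measured
#' variables: an ANCOVA with subject as a factor and a common slope, giving
#' `r_rm = Sxy / sqrt(Sxx * Syy)` on subject-centred data with
#' `N - k - 1` error degrees of freedom (k subjects). With a single subject
#' this reduces exactly to the Pearson correlation with `N - 2` df. The
#' two-sided p value comes from `t = r * sqrt(df / (1 - r^2))`.
#'
#' `r_rm` is invariant to per-subject location shifts in either variable,
#' which is the point: it measures whether x and y move together within
#' subjects, ignoring between-subject differences in level.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names of the paired measurements.
#' @param subject Unquoted column name of the subject/grouping factor.
#' @return One-row tibble: `r`, `df`, `p`, `slope`, `n_obs`, `n_subjects`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   s = rep(c("a", "b"), each = 4),
#'   x = c(1, 2, 3, 4, 11, 12, 13, 14),
#'   y = c(2, 3, 4, 5, 1, 2, 3, 4)
#' )
#' rmcorr(d, x, y, s)
rmcorr <- function(data, x, y, subject) {
  x <- dplyr::pull(data, {{ x }})
  y <- dplyr::pull(data, {{ y }})
  subject <- as.character(dplyr::pull(data, {{ subject }}))
  ok <- is.finite(x) & is.finite(y) & !is.na(subject)
  x <- x[ok]; y <- y[ok]; subject <- subject[ok]
  n <- length(x)
  k <- length(unique(subject))
  if (n < 4) abort_bad_arg("need at least 4 complete observations.")

  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  sxx <- sum(xc^2)
  syy <- sum(yc^2)
  sxy <- sum(xc * yc)
  if (sxx <= 0) abort_bad_arg("x is constant within every subject.")
  if (syy <= 0) abort_bad_arg("y is constant within every subject.")
  r <- sxy / sqrt(sxx * syy)
  df <- n - k - 1
  if (df < 1) abort_bad_arg("not enough within-subject replication (df < 1).")
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tval), df = df)
  }
  tibble(r = r, df = df, p = p, slope = sxy / sxx,
         n_obs = n, n_subjects = k)
}

# Hartigan & Hartigan's dip statistic: the smallest sup-norm distance between
# the empirical CDF and any unimodal CDF, computed by the iterative greatest
# convex minorant / least concave majorant algorithm on the sorted sample.
# All interior quantities are in observation-count units; the returned dip is
# divided by 2n. A constant sample is degenerate (a point mass is unimodal)
# and returns 0.
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 2 || x[n] == x[1]) return(0)

  # mn[j]: previous contact point of the greatest convex minorant up to j
  mn <- integer(n)
  mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) <
          (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # mj[j]: next contact point of the least concave majorant from j on
  mj <- integer(n)
  mj[n] <- n
  for (j in (n - 1):1) {
    mj[j] <- j + 1L
    repeat {
      mjk <- mj[j]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[j] - x[mjk]) * (mjk - mjmjk) <
          (x[mjk] - x[mjmjk]) * (j - mjk)) break
      mj[j] <- mjmjk
    }
  }

  low <- 1L
  high <- n
  dip_c <- 1 # lower bound: 1/(2n) after scaling

  repeat {
    gcm <- integer(0)
    gcm[1] <- high
    k <- 1L
    while (gcm[k] > low) {
      gcm[k + 1L] <- mn[gcm[k]]
      k <- k + 1L
    }
    l_gcm <- k
    ig <- k
    ix <- ig - 1L

    lcm <- integer(0)
    lcm[1] <- low
    k <- 1L
    while (lcm[k] < high) {
      lcm[k + 1L] <- mj[lcm[k]]
      k <- k + 1L
    }
    l_lcm <- k
    ih <- k
    iv <- 2L

    # largest vertical gap between the two curves on [low, high]
    d <- 0
    if (l_gcm != 2L || l_lcm != 2L) {
      repeat {
        gcmix <- gcm[ix]
        lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv - 1L
          }
        } else {
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv
          }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    }

    if (d < dip_c) break

    # largest deviation of the empirical CDF below the GCM on [low, gcm[ig]]
    dip_l <- 0
    if (ig < l_gcm) {
      for (j in ig:(l_gcm - 1L)) {
        jb <- gcm[j + 1L]
        je <- gcm[j]
        max_t <- 1
        if (je - jb > 1L && x[je] != x[jb]) {
          C <- (je - jb) / (x[je] - x[jb])
          for (jj in jb:je) {
            t <- (jj - jb + 1) - (x[jj] - x[jb]) * C
            if (max_t < t) max_t <- t
          }
        }
        if (dip_l < max_t) dip_l <- max_t
      }
    }
    # largest deviation above the LCM on [lcm[ih], high]
    dip_u <- 0
    if (ih < l_lcm) {
      for (j in ih:(l_lcm - 1L)) {
        jb <- lcm[j]
        je <- lcm[j + 1L]
        max_t <- 1
        if (je - jb > 1L && x[je] != x[jb]) {
          C <- (je - jb) / (x[je] - x[jb])
          for (jj in jb:je) {
            t <- -((jj - jb - 1) - (x[jj] - x[jb]) * C)
            if (max_t < t) max_t <- t
          }
        }
        if (dip_u < max_t) dip_u <- max_t
      }
    }

    dip_new <- max(dip_l, dip_u)
    if (dip_c < dip_new) dip_c <- dip_new
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }
  dip_c / (2 * n)
}

#' Hartigan's dip test of unimodality
#'
#' Computes the dip statistic -- the smallest sup-norm distance between the
#' empirical CDF and the class of unimodal CDFs -- and a Monte-Carlo p value
#' against samples of the same size from the uniform distribution, the
#' least-favourable unimodal null (the classical calibration of the test).
#' The statistic is invariant under affine transformations of the sample but
#' does depend on the spacings, not only the ranks.
#'
#' @param x Numeric sample (at least 4 values).
#' @param n_null Number of uniform null samples for the p value.
#' @param seed Optional RNG seed.
#' @param null_dips Optional precomputed vector of null dip statistics for
#'   this sample size (e.g. from [dip_null_distribution()]), overriding
#'   `n_null`.
#' @return One-row tibble: `dip`, `p`, `n`, `n_null`.
#' @export
hartigan_dip <- function(x, n_null = 2000, seed = NULL, null_dips = NULL) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) abort_bad_arg("need at least 4 observations for the dip test.")
  obs <- dip_stat(x)
  if (is.null(null_dips)) {
    n_null <- check_count(n_null, "n_null", min = 1L)
    null_dips <- dip_null_distribution(n, n_null = n_null, seed = seed)
  }
  tibble(
    dip = obs,
    p = (1 + sum(null_dips >= obs)) / (length(null_dips) + 1),
    n = n, n_null = length(null_dips)
  )
}

#' Null distribution of the dip statistic for a given sample size
#'
#' Simulates the dip statistic for uniform samples of size `n`. Precompute
#' once and pass to [hartigan_dip()] when testing many samples of the same
#' size.
#'
#' @param n Sample size.
#' @param n_null Number of simulations.
#' @param seed Optional RNG seed.
#' @return Numeric vector of null dip values.
#' @export
dip_null_distribution <- function(n, n_null = 2000, seed = NULL) {
  n <- check_count(n, "n", min = 4L)
  n_null <- check_count(n_null, "n_null", min = 1L)
  with_seed(seed, {
    vapply(seq_len(n_null), function(i) dip_stat(runif(n)), numeric(1))
  })
}
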