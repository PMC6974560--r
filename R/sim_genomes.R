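#' Simulate genome feature tables with planted CUE effects
#'
#' Generates a taxon x KO count table with phylogenetic autocorrelation and a
#' prevalence gradient, plus a CUE trait constructed from a chosen subset of
#' "causal" KOs. Latent per-Mbp log densities combine a KO-specific baseline,
#' a Brownian component on the tree, and independent noise; each KO is then
#' zero-truncated so that it is present in a target fraction of genomes
#' (drawn from `prevalence_range`), which creates the rare-function tail the
#' prevalence filter is meant to remove. Counts are the latent density times
#' genome size with optional negative-binomial overdispersion.
#'
#' CUE is `cue_baseline + sum(effect_k * z_k) + noise`, where `z_k` is the
#' causal KO's realised density standardised across taxa (so `effect_size` is
#' in CUE units per standard deviation of density), and the noise has a
#' Brownian component on the tree plus an independent component. Measured CUE
#' is dominated by assay-level variation rather than phylogeny, so the
#' independent component is the larger one by default. Causal KOs are forced
#' to be present in every genome. The result is clipped to (0.01, 0.99).
#'
#' @param tree A rooted `ape::phylo` tree; its tips are the taxa.
#' @param n_kos Number of KO features.
#' @param n_causal Number of causal KOs (at most `n_kos`).
#' @param effect_size Effect per causal KO, CUE units per SD of density;
#'   scalar (signs alternate) or vector of length `n_causal`.
#' @param causal_cor Correlation of the causal KOs' latent log densities via
#'   a shared factor (co-occurring pathway genes). 0 makes them independent;
#'   with several markers of the same sign, a shared factor is what makes
#'   each marker's *marginal* association strong enough to detect, because
#'   independent causal features act as residual noise in one another's
#'   single-predictor tests.
#' @param density_dispersion Negative-binomial overdispersion of counts
#'   (0 = Poisson).
#' @param genome_size_range Range of genome sizes, Mbp.
#' @param prevalence_range Range of the fraction of genomes carrying a KO.
#' @param cue_baseline Mean CUE.
#' @param noise_sd_phylo,noise_sd_iid Standard deviations of the Brownian and
#'   independent CUE noise components.
#' @param seed Optional RNG seed.
#' @return A list: `features` (tibble: `taxon`, `genome_size_mbp`, KO count
#'   columns), `cue` (tibble: `taxon`, `value`), `causal` (tibble: `feature`,
#'   `effect`), and `linear_predictor` (named vector, before noise).
#' @export
simulate_genomes <- function(tree, n_kos = 200, n_causal = 5,
                             effect_size = 0.03,
                             causal_cor = 0,
                             density_dispersion = 0.05,
                             genome_size_range = c(2, 8),
                             prevalence_range = c(0.15, 1),
                             cue_baseline = 0.55,
                             noise_sd_phylo = 0.02,
                             noise_sd_iid = 0.03,
                             seed = NULL) {
  n_kos <- check_count(n_kos, "n_kos", min = 1L)
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  if (n_causal > n_kos) abort_bad_arg("`n_causal` cannot exceed `n_kos`.")
  if (any(genome_size_range <= 0)) abort_bad_arg("genome sizes must be positive.")
  n <- length(tree$tip.label)
  effects <- if (n_causal == 0) numeric(0) else {
    if (length(effect_size) == 1) {
      effect_size * rep_len(c(1, -1), n_causal)
    } else if (length(effect_size) == n_causal) {
      effect_size
    } else {
      abort_bad_arg("`effect_size` must be scalar or length `n_causal`.")
    }
  }

  V <- vcv_matrix(tree)
  T_depth <- max(diag(V))
  L_unit <- t(chol(V / T_depth)) # unit-marginal-variance Brownian draws

  with_seed(seed, {
    genome_size <- runif(n, genome_size_range[1], genome_size_range[2])
    ko_ids <- sprintf("K%05d", seq_len(n_kos))
    causal_idx <- seq_len(n_causal)

    base <- rnorm(n_kos, log(5), 0.7)
    phylo_part <- L_unit %*% matrix(rnorm(n * n_kos), n, n_kos) * 0.4
    iid_part <- matrix(rnorm(n * n_kos, 0, 0.3), n, n_kos)
    latent <- sweep(phylo_part + iid_part, 2, base, "+")
    if (n_causal > 1 && causal_cor > 0) {
      # shared latent factor with the same phylogenetic/independent mixture
      shared <- 0.4 * drop(L_unit %*% rnorm(n)) + rnorm(n, 0, 0.3)
      for (j in causal_idx) {
        own <- 0.4 * drop(L_unit %*% rnorm(n)) + rnorm(n, 0, 0.3)
        latent[, j] <- base[j] + sqrt(causal_cor) * shared +
          sqrt(1 - causal_cor) * own
      }
    }

    prevalence <- runif(n_kos, prevalence_range[1], prevalence_range[2])
    prevalence[causal_idx] <- 1
    density <- exp(latent)
    for (k in seq_len(n_kos)) {
      n_absent <- round((1 - prevalence[k]) * n)
      if (n_absent > 0) {
        density[order(latent[, k])[seq_len(n_absent)], k] <- 0
      }
    }

    mean_counts <- sweep(density, 1, genome_size, "*")
    counts <- if (density_dispersion > 0) {
      matrix(
        rnbinom(n * n_kos, mu = mean_counts, size = 1 / density_dispersion),
        n, n_kos
      )
    } else {
      matrix(stats::rpois(n * n_kos, mean_counts), n, n_kos)
    }
    counts[mean_counts == 0] <- 0L
    colnames(counts) <- ko_ids

    lp <- rep(0, n)
    if (n_causal > 0) {
      for (j in causal_idx) {
        dj <- counts[, j] / genome_size
        sdj <- sd(dj)
        if (sdj > 0) lp <- lp + effects[j] * (dj - mean(dj)) / sdj
      }
    }
    noise <- noise_sd_phylo * drop(L_unit %*% rnorm(n)) + rnorm(n, 0, noise_sd_iid)
    cue <- pmin(pmax(cue_baseline + lp + noise, 0.01), 0.99)

    features <- dplyr::bind_cols(
      tibble(taxon = tree$tip.label, genome_size_mbp = genome_size),
      as_tibble(counts)
    )
    list(
      features = features,
      cue = tibble(taxon = tree$tip.label, value = cue),
      causal = tibble(feature = ko_ids[causal_idx], effect = effects),
      linear_predictor = setNames(lp, tree$tip.label)
    )
  })
}

#' Simulate a complete explore/validate marker study
#'
#' Builds every input of the genomic-marker pipeline with known ground truth:
#' a tree, a genome feature table with planted causal KOs, CUE traits on
#' glucose plus three validation substrates (the causal effects are shared
#' across substrates; the noise draws are independent), a designated
#' exploration taxon subset, and a community (microcosm-style) data set of
#' KO relative abundances paired with community CUE.
#'
#' The planted markers are a co-occurring function set (all effects positive,
#' latent densities sharing a pathway factor, correlation 0.85): with several
#' markers of the same sign this is what keeps each marker's *marginal*
#' single-predictor association detectable -- independent causal features
#' would act as residual noise in one another's tests and cap the achievable
#' marginal power well below the target at these sample sizes.
#'
#' The planted slope is set from the two-sided power calculation for the
#' marginal test of one marker, accounting for the other markers' shared and
#' independent contributions. With k equicorrelated standardised densities
#' (realised pairwise correlation r, a generator design constant measured at
#' 0.55 for the default dispersion), the marginal slope of one marker is
#' `beta * c1` with `c1 = 1 + (k-1) r` and the residual variance is
#' `noise_sd^2 + beta^2 (v - c1^2)` with `v = k + k(k-1) r`, giving
#' `beta = delta * noise_sd * sqrt(e) / sqrt(c1^2 (n_explore + delta^2) -
#' delta^2 v)` where `delta = z_{1-alpha/2} + z_{power}` and `e = 1.3` is the
#' pilot-measured design effect of the screen (variance inflation of the
#' PGLS slope relative to iid ordinary least squares, from the phylogenetic
#' structure of densities and noise and from profiling lambda).
#'
#' @param n_taxa,n_explore Total taxa and size of the exploration subset.
#' @param n_kos,n_causal Feature counts, as in [simulate_genomes()].
#' @param power_target Nominal power of the exploratory test for each causal
#'   KO (about 0.9).
#' @param alpha Significance level the power calculation refers to.
#' @param substrates Names of the three validation substrates.
#' @param n_communities Number of simulated communities.
#' @param community_noise_sd SD of community CUE noise around its planted
#'   linear predictor (communities respond strongly to the causal functions).
#' @param noise_sd_phylo,noise_sd_iid CUE noise components, as in
#'   [simulate_genomes()].
#' @param seed RNG seed for the whole study.
#' @return A list: `tree`, `features`, `cue_tables` (named list of trait
#'   tibbles: glucose + validation substrates), `community` (tibble:
#'   `community`, `cue`, KO relative-abundance columns), `explore_taxa`,
#'   `causal`, `effect_size`.
#' @export
simulate_marker_study <- function(n_taxa = 40, n_explore = 20,
                                  n_kos = 2000, n_causal = 5,
                                  power_target = 0.93, alpha = 0.05,
                                  substrates = c("pdb", "pyruvate", "succinate"),
                                  n_communities = 10,
                                  community_noise_sd = 0.01,
                                  noise_sd_phylo = 0.02,
                                  noise_sd_iid = 0.03,
                                  seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 6 + length(substrates))
  tree <- simulate_tree(n_taxa, seed = seeds[1])
  noise_sd <- sqrt(noise_sd_phylo^2 + noise_sd_iid^2)
  causal_cor <- 0.85
  realized_r <- 0.55 # pairwise correlation of standardised causal densities
  design_effect <- 1.3 # PGLS slope variance inflation vs iid OLS (pilot)
  effect <- if (n_causal > 0) {
    delta <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power_target)
    c1 <- 1 + (n_causal - 1) * realized_r
    v <- n_causal + n_causal * (n_causal - 1) * realized_r
    denom2 <- c1^2 * (n_explore + delta^2) - delta^2 * v
    if (denom2 <= 0) {
      abort_bad_arg("power target infeasible at this exploration size.")
    }
    delta * noise_sd * sqrt(design_effect) / sqrt(denom2)
  } else 0

  g <- simulate_genomes(
    tree, n_kos = n_kos, n_causal = n_causal,
    effect_size = rep(effect, n_causal), causal_cor = causal_cor,
    noise_sd_phylo = noise_sd_phylo, noise_sd_iid = noise_sd_iid,
    seed = seeds[2]
  )
  effects <- setNames(g$causal$effect, g$causal$feature)

  # validation substrates: same causal linear predictor, fresh noise
  V <- vcv_matrix(tree)
  L_unit <- t(chol(V / max(diag(V))))
  cue_tables <- list(glucose = g$cue)
  for (i in seq_along(substrates)) {
    noise <- with_seed(seeds[2 + i], {
      noise_sd_phylo * drop(L_unit %*% rnorm(n_taxa)) +
        rnorm(n_taxa, 0, noise_sd_iid)
    })
    cue_tables[[substrates[i]]] <- tibble(
      taxon = tree$tip.label,
      value = pmin(pmax(0.55 + g$linear_predictor + noise, 0.01), 0.99)
    )
  }

  explore_taxa <- with_seed(seeds[3 + length(substrates)], {
    sort(sample(tree$tip.label, n_explore))
  })

  community <- with_seed(seeds[4 + length(substrates)], {
    abund <- matrix(rlnorm(n_communities * n_kos, log(5), 0.5),
                    n_communities, n_kos)
    colnames(abund) <- sprintf("K%05d", seq_len(n_kos))
    if (n_causal > 1) {
      # causal functions co-occur in communities too (same pathway factor)
      shared <- rnorm(n_communities)
      for (f in g$causal$feature) {
        own <- rnorm(n_communities)
        abund[, f] <- exp(log(5) + 0.5 * (sqrt(causal_cor) * shared +
                                            sqrt(1 - causal_cor) * own))
      }
    }
    rel <- abund / rowSums(abund)
    lp <- rep(0, n_communities)
    for (f in names(effects)) {
      z <- scale(rel[, f])[, 1]
      lp <- lp + effects[[f]] * z
    }
    cue_c <- pmin(pmax(0.5 + lp + rnorm(n_communities, 0, community_noise_sd),
                       0.01), 0.99)
    dplyr::bind_cols(
      tibble(community = sprintf("mc%02d", seq_len(n_communities)),
             cue = cue_c),
      as_tibble(rel)
    )
  })

  list(
    tree = tree, features = g$features, cue_tables = cue_tables,
    community = community, explore_taxa = explore_taxa,
    causal = g$causal, effect_size = effect
  )
}
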