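test_that("density standardisation and the prevalence filter follow their rules", {
  f <- tibble::tibble(
    taxon = c("t1", "t2", "t3", "t4"), genome_size_mbp = c(5, 2, 4, 4),
    K1 = c(10, 4, 0, 0), K2 = c(0, 0, 2, 0), K3 = c(1, 1, 1, 1)
  )
  d <- standardize_density(f)
  expect_equal(d$K1, c(2, 2, 0, 0))
  expect_equal(d$K3, 1 / f$genome_size_mbp)

  expect_named(prevalence_filter(f, 2), c("taxon", "genome_size_mbp", "K1", "K3"))
  expect_named(prevalence_filter(f, 1), names(f)) # identity at min 1
  f0 <- dplyr::mutate(f, K4 = 0)
  expect_false("K4" %in% names(prevalence_filter(f0, 1)))
  expect_error(standardize_density(dplyr::select(f, -genome_size_mbp)),
               "genome_size_mbp")
})

test_that("exploration finds a strongly planted marker with the right sign", {
  st <- simulate_marker_study(n_taxa = 30, n_explore = 30, n_kos = 60,
                              n_causal = 2, power_target = 0.995, seed = 51)
  dens <- standardize_density(prevalence_filter(st$features, 4))
  cand <- explore_markers(dens, st$cue_tables$glucose, st$tree,
                          st$explore_taxa)
  hit <- cand[cand$feature %in% st$causal$feature, ]
  expect_true(all(hit$candidate))
  expect_equal(hit$direction, sign(st$causal$effect))
  # rare features are never tested
  expect_false(any(setdiff(names(st$features), names(dens)) %in% cand$feature))
  expect_error(explore_markers(dens, st$cue_tables$glucose, st$tree,
                               st$explore_taxa[1:4]), "at least 6")
})

test_that("substrate validation requires same-direction significance in >= 2 of 3", {
  st <- simulate_marker_study(n_taxa = 30, n_explore = 30, n_kos = 60,
                              n_causal = 2, power_target = 0.995, seed = 52)
  dens <- standardize_density(prevalence_filter(st$features, 4))
  cand <- explore_markers(dens, st$cue_tables$glucose, st$tree, st$explore_taxa)
  others <- st$cue_tables[c("pdb", "pyruvate", "succinate")]
  v <- validate_other_substrates(cand, dens, others, st$tree)
  planted <- v[v$feature %in% st$causal$feature, ]
  expect_true(all(planted$validated_substrates))

  # flipping the validation traits destroys the direction match
  flipped <- lapply(others, function(tt) dplyr::mutate(tt, value = 1 - value))
  vf <- validate_other_substrates(cand, dens, flipped, st$tree)
  plf <- vf[vf$feature %in% st$causal$feature, ]
  expect_false(any(plf$validated_substrates))

  # dropping a substrate keeps the required count unchanged
  v2 <- validate_other_substrates(cand, dens, others[1:2], st$tree)
  expect_true(all(v2$n_substrates_confirming[v2$candidate] <= 2))
})

test_that("microcosm validation is monotone-rank based with sign matching", {
  cand <- tibble::tibble(
    feature = c("Kup", "Kdown", "Kflat"),
    slope = c(1, -1, 1), p = 0.01, lambda = 0, se = 1, statistic = 1,
    loglik = 0, direction = c(1, -1, 1), candidate = TRUE
  )
  comm <- tibble::tibble(
    community = sprintf("c%d", 1:8), cue = (1:8) / 10,
    Kup = (1:8) / 8,          # perfectly increasing with cue
    Kdown = (1:8) / 8,        # increasing, but explored as negative
    Kflat = rep(0.5, 8)       # constant: cannot be ranked
  )
  v <- validate_microcosm(cand, comm)
  expect_equal(v$microcosm_rho[v$feature == "Kup"], 1)
  expect_true(v$validated_microcosm[v$feature == "Kup"])
  expect_false(v$validated_microcosm[v$feature == "Kdown"]) # wrong sign
  expect_false(v$validated_microcosm[v$feature == "Kflat"]) # undefined rho
  expect_true(is.na(v$microcosm_rho[v$feature == "Kflat"]))
  expect_error(validate_microcosm(cand, comm[1:3, ]), "5 communities")
})

test_that("finalisation needs every tier and the venn regions partition", {
  st <- simulate_marker_study(n_taxa = 30, n_explore = 20, n_kos = 80,
                              n_causal = 3, power_target = 0.995, seed = 53)
  res <- run_marker_pipeline(st$tree, st$features, st$cue_tables,
                             st$community, st$explore_taxa,
                             n_perm = 199, seed = 5)
  m <- res$markers
  # final implies every gate
  expect_true(all(m$full_pass[m$final]))
  expect_true(all(m$validated_substrates[m$final]))
  expect_true(all(m$validated_microcosm[m$final]))
  expect_true(all(m$residual_pass[m$final]))
  # validated_any is the weaker (either-route) tier
  expect_true(all(m$validated_any[m$final]))
  # candidates passing exploration alone are not finalized
  only_explore <- m$candidate & !m$validated_substrates & !m$validated_microcosm
  expect_false(any(m$final[only_explore]))
  # venn regions partition the candidate set
  expect_equal(sum(res$report$n), sum(m$candidate))
  # without community data nothing reaches the final tier
  res0 <- run_marker_pipeline(st$tree, st$features, st$cue_tables, NULL,
                              st$explore_taxa, n_perm = 199, seed = 5)
  expect_equal(sum(res0$markers$final), 0)
})

test_that("a priori hypothesis table handles transforms, skips and recovery", {
  tr <- simulate_tree(24, seed = 61)
  set.seed(62)
  g <- 0:4
  d <- tibble::tibble(
    taxon = tr$tip.label,
    max_growth_rate = runif(24, 0.05, 0.6),
    rrn = 2^sample(g, 24, replace = TRUE),
    flat = 1
  )
  d$cue <- 0.3 + 0.5 * d$max_growth_rate + rnorm(24, 0, 0.03)
  d$log2_rrn <- log2(d$rrn)
  hyp <- tibble::tibble(
    response = c("cue", "cue", "cue", "cue"),
    predictor = c("max_growth_rate", "log2_rrn", "flat", "missing_col")
  )
  tab <- test_a_priori_hypotheses(d, tr, hyp)
  expect_equal(nrow(tab), 4)
  gr <- tab[tab$predictor == "max_growth_rate", ]
  expect_gt(gr$slope, 0)
  expect_lt(gr$p, 0.01)
  expect_equal(tab$skipped[tab$predictor == "flat"], "constant predictor")
  expect_equal(tab$skipped[tab$predictor == "missing_col"], "missing column")
  # log2 reparameterisation: slope on log2(rrn) equals slope on the exponent
  d$g_exp <- log2(d$rrn)
  t1 <- test_a_priori_hypotheses(d, tr, tibble::tibble(response = "cue",
                                                       predictor = "log2_rrn"))
  t2 <- test_a_priori_hypotheses(d, tr, tibble::tibble(response = "cue",
                                                       predictor = "g_exp"))
  expect_equal(t1$slope, t2$slope, tolerance = 1e-10)
})
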