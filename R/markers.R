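# Explore/validate pipeline for genomic markers of CUE.
#
# The screen mirrors a two-stage comparative-genomics design: candidate
# markers are proposed by per-feature PGLS on an exploration subset of taxa
# (raw alpha, no multiplicity correction), then asked to reproduce -- with
# the same direction -- in the full glucose data, in at least two of three
# other substrates, and in an independent community data set. Requiring the
# same signed, significant association across data sets is the design's
# implicit false-discovery control.

#' Genome-size standardised feature densities
#'
#' Divides every feature count by genome size, giving densities per Mbp.
#'
#' @param features Wide tibble: `taxon`, `genome_size_mbp`, feature count
#'   columns.
#' @param genome_size_col Name of the genome size column.
#' @return Tibble of the same shape with densities instead of counts.
#' @export
standardize_density <- function(features, genome_size_col = "genome_size_mbp") {
  if (!genome_size_col %in% names(features)) {
    abort_bad_arg(sprintf("missing `%s` column.", genome_size_col))
  }
  gs <- features[[genome_size_col]]
  if (any(gs <= 0)) abort_bad_arg("genome sizes must be positive.")
  feature_cols <- setdiff(names(features), c("taxon", genome_size_col))
  features |>
    dplyr::mutate(dplyr::across(dplyr::all_of(feature_cols), ~ .x / gs))
}

#' Remove rare features
#'
#' Keeps features present (nonzero) in at least `min_prevalence` taxa. Rare
#' functions found in just a few genomes produce unstable regression slopes
#' and are removed before testing.
#'
#' @param features Wide tibble of counts or densities (non-feature columns
#'   `taxon` and `genome_size_mbp` are kept as-is).
#' @param min_prevalence Minimum number of carrier taxa.
#' @return The tibble with rare feature columns dropped.
#' @export
prevalence_filter <- function(features, min_prevalence = 4) {
  min_prevalence <- check_count(min_prevalence, "min_prevalence", min = 1L)
  keep_cols <- intersect(c("taxon", "genome_size_mbp"), names(features))
  feature_cols <- setdiff(names(features), keep_cols)
  prev <- vapply(features[feature_cols], function(x) sum(x != 0), integer(1))
  dplyr::select(
    features,
    dplyr::all_of(c(keep_cols, feature_cols[prev >= min_prevalence]))
  )
}

# internal: features tibble -> matrix aligned to taxa
feature_matrix <- function(features, taxa) {
  feature_cols <- setdiff(names(features), c("taxon", "genome_size_mbp"))
  m <- as.matrix(features[feature_cols])
  rownames(m) <- features$taxon
  m[taxa, , drop = FALSE]
}

#' Exploratory per-feature PGLS screen
#'
#' Fits `cue ~ density` by PGLS (lambda profiled per feature) for every
#' feature on the exploration subset of taxa and flags candidates whose slope
#' is significant at `alpha`, recording the direction.
#'
#' @param densities Standardised density tibble (after
#'   [standardize_density()] and [prevalence_filter()]).
#' @param cue Trait tibble or named vector of CUE on the exploration
#'   substrate.
#' @param tree Phylogeny covering all taxa.
#' @param explore_taxa Character vector of exploration taxa (at least 6).
#' @param alpha Candidate threshold for the slope p value.
#' @param lambda_grid Lambda grid of the profiled screen.
#' @param criterion Lambda profile criterion, `"reml"` (default; less biased
#'   lambda estimates and a better-calibrated slope test at screen sample
#'   sizes) or `"ml"`.
#' @param p_adjust `"none"` (default: raw per-feature alpha, matching the
#'   historical explore/validate design, whose false-discovery control is the
#'   downstream validation conjunction) or `"BH"` for Benjamini-Hochberg
#'   adjustment of the exploration p values before thresholding.
#' @return Tibble with one row per tested feature: `feature`, `slope`, `p`,
#'   `lambda`, `direction` (+1/-1), `candidate`.
#' @export
explore_markers <- function(densities, cue, tree, explore_taxa,
                            alpha = 0.05,
                            lambda_grid = seq(0, 1, by = 0.05),
                            criterion = c("reml", "ml"),
                            p_adjust = c("none", "BH")) {
  criterion <- match.arg(criterion)
  p_adjust <- match.arg(p_adjust)
  if (length(explore_taxa) < 6) {
    abort_bad_arg("need at least 6 exploration taxa for a stable PGLS screen.")
  }
  if (!all(explore_taxa %in% tree$tip.label)) {
    abort_bad_arg("`explore_taxa` must be a subset of the tree tips.")
  }
  y_all <- as_trait_vector(cue)
  if (!all(explore_taxa %in% names(y_all))) {
    abort_bad_arg("missing CUE values for some exploration taxa.")
  }
  sub_tree <- ape::keep.tip(tree, explore_taxa)
  cache <- phylo_cache(sub_tree)
  y <- y_all[cache$labels]
  X <- feature_matrix(densities, cache$labels)
  res <- pgls_screen(cache, y, X, lambda_grid = lambda_grid,
                     criterion = criterion)
  p_thresh <- if (p_adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res |>
    dplyr::mutate(
      direction = sign(.data$slope),
      candidate = is.finite(p_thresh) & p_thresh <= alpha
    )
}

#' Validate candidates on the other substrates
#'
#' Re-screens each candidate feature against CUE measured on the validation
#' substrates, over the full taxon set, and requires a significant slope with
#' the exploration direction in at least `min_substrates` of them. A missing
#' substrate is skipped without changing the required count.
#'
#' @param candidates Output of [explore_markers()] (only rows with
#'   `candidate = TRUE` are evaluated).
#' @param densities,tree As in [explore_markers()].
#' @param cue_by_substrate Named list of trait tibbles, one per validation
#'   substrate.
#' @param alpha Significance threshold.
#' @param min_substrates Minimum number of confirming substrates.
#' @param lambda_grid,criterion As in [explore_markers()].
#' @return `candidates` with columns `n_substrates_confirming` and
#'   `validated_substrates`.
#' @export
validate_other_substrates <- function(candidates, densities, cue_by_substrate,
                                      tree, alpha = 0.05, min_substrates = 2,
                                      lambda_grid = seq(0, 1, by = 0.05),
                                      criterion = c("reml", "ml")) {
  criterion <- match.arg(criterion)
  cand <- candidates$feature[candidates$candidate]
  confirm <- setNames(integer(length(cand)), cand)
  cue_by_substrate <- purrr::compact(cue_by_substrate)
  for (sub in names(cue_by_substrate)) {
    y_all <- as_trait_vector(cue_by_substrate[[sub]])
    taxa <- intersect(tree$tip.label, names(y_all))
    sub_tree <- if (length(taxa) < length(tree$tip.label)) {
      ape::keep.tip(tree, taxa)
    } else tree
    cache <- phylo_cache(sub_tree)
    X <- feature_matrix(densities, cache$labels)[, cand, drop = FALSE]
    res <- pgls_screen(cache, y_all[cache$labels], X,
                       lambda_grid = lambda_grid, criterion = criterion)
    dir0 <- candidates$direction[match(cand, candidates$feature)]
    hit <- is.finite(res$p) & res$p <= alpha & sign(res$slope) == dir0
    confirm[cand] <- confirm[cand] + as.integer(hit)
  }
  candidates |>
    dplyr::mutate(
      n_substrates_confirming =
        ifelse(.data$candidate, confirm[.data$feature], NA_integer_),
      validated_substrates =
        .data$candidate & confirm[.data$feature] >= min_substrates
    )
}

#' Validate candidates against community (microcosm) data
#'
#' Spearman rank correlation between each candidate feature's relative
#' abundance across communities and community CUE; a candidate passes when
#' the correlation is significant at `alpha` with the exploration direction.
#' Features constant across communities cannot be ranked and fail with a
#' recorded reason.
#'
#' @param candidates Output of [explore_markers()] or
#'   [validate_other_substrates()].
#' @param community Tibble: `community`, `cue`, feature relative-abundance
#'   columns (at least 5 communities).
#' @param alpha Significance threshold.
#' @return `candidates` with `microcosm_rho`, `microcosm_p`,
#'   `validated_microcosm`.
#' @export
validate_microcosm <- function(candidates, community, alpha = 0.05) {
  if (nrow(community) < 5) abort_bad_arg("need at least 5 communities.")
  cand <- candidates$feature[candidates$candidate]
  rho <- setNames(rep(NA_real_, length(cand)), cand)
  pval <- rho
  for (f in cand) {
    if (!f %in% names(community)) next
    x <- community[[f]]
    if (var(x) == 0 || var(community$cue) == 0) next # undefined rank correlation
    ct <- suppressWarnings(
      cor.test(x, community$cue, method = "spearman", exact = FALSE)
    )
    rho[f] <- unname(ct$estimate)
    pval[f] <- ct$p.value
  }
  dir0 <- setNames(candidates$direction[match(cand, candidates$feature)], cand)
  ok <- !is.na(rho) & !is.na(pval) & pval <= alpha & sign(rho) == dir0
  candidates |>
    dplyr::mutate(
      microcosm_rho = ifelse(.data$candidate, rho[.data$feature], NA_real_),
      microcosm_p = ifelse(.data$candidate, pval[.data$feature], NA_real_),
      validated_microcosm = .data$candidate &
        !is.na(ok[.data$feature]) & ok[.data$feature]
    )
}

#' Finalize markers and build the validation report
#'
#' Re-fits each candidate against the full glucose data set (exploration plus
#' validation taxa) requiring a same-direction significant slope, runs the
#' residual phylogenetic-signal check on those full-data fits, and assembles
#' the two validation tiers:
#'
#' * `validated_any`: confirmed by the other-substrates route or the
#'   community route (plus full-glucose agreement and a clean residual
#'   check) -- the tier a marker table would list;
#' * `final`: confirmed by *both* routes ("uniformly validated") -- the
#'   stringent tier under which chance candidates are essentially never
#'   confirmed.
#'
#' @param candidates Output of the two validation steps.
#' @param densities,tree As in [explore_markers()].
#' @param cue_full Full-data glucose CUE (trait tibble or named vector).
#' @param alpha Significance threshold.
#' @param n_perm Permutations for the residual K test.
#' @param seed Optional RNG seed for the residual check.
#' @param lambda_method Lambda mode for the per-candidate full-data fits
#'   (`"REML"` or `"ML"`).
#' @return A list: `markers` (the candidate table with `full_pass`,
#'   `residual_pass`, `validated_any`, `final`) and `report` (Venn-style
#'   region counts by direction, see [venn_report()]).
#' @export
finalize_markers <- function(candidates, densities, cue_full, tree,
                             alpha = 0.05, n_perm = 999, seed = NULL,
                             lambda_method = "REML") {
  needed <- c("validated_substrates", "validated_microcosm")
  if (!all(needed %in% names(candidates))) {
    abort_bad_arg("run validate_other_substrates() and validate_microcosm() first.")
  }
  y_all <- as_trait_vector(cue_full)
  cand <- candidates$feature[candidates$candidate]
  full_pass <- setNames(logical(length(cand)), cand)
  residual_pass <- setNames(rep(NA, length(cand)), cand)
  seeds <- if (length(cand)) derive_seeds(seed %||% 1L, length(cand)) else integer(0)

  dens_df <- as_tibble(densities)
  for (i in seq_along(cand)) {
    f <- cand[i]
    d <- tibble(
      taxon = dens_df$taxon,
      cue = unname(y_all[dens_df$taxon]),
      x = dens_df[[f]]
    )
    fit <- tryCatch(pgls_fit(d, cue ~ x, tree, lambda = lambda_method),
                    error = function(e) NULL)
    if (is.null(fit)) next
    co <- tidy(fit)
    slope <- co$estimate[co$term == "x"]
    pv <- co$p.value[co$term == "x"]
    dir0 <- candidates$direction[match(f, candidates$feature)]
    full_pass[f] <- is.finite(pv) && pv <= alpha && sign(slope) == dir0
    if (full_pass[f]) {
      chk <- suppressWarnings(
        residual_phylosig_check(fit, n_perm = n_perm, seed = seeds[i],
                                alpha = alpha)
      )
      residual_pass[f] <- chk$pass
    }
  }

  markers <- candidates |>
    dplyr::mutate(
      full_pass = .data$candidate & !is.na(full_pass[.data$feature]) &
        full_pass[.data$feature],
      residual_pass = residual_pass[.data$feature],
      validated_any = .data$full_pass &
        (.data$validated_substrates | .data$validated_microcosm) &
        !is.na(.data$residual_pass) & .data$residual_pass,
      final = .data$full_pass &
        .data$validated_substrates & .data$validated_microcosm &
        !is.na(.data$residual_pass) & .data$residual_pass
    )
  list(markers = markers, report = venn_report(markers))
}

#' Venn-style overlap report for marker candidates
#'
#' Counts exploration candidates by their membership in the three validating
#' data sets (full glucose, other substrates, microcosm), split by direction.
#' The region counts partition the candidate set, so they sum to the
#' per-data-set totals.
#'
#' @param markers Marker table from [finalize_markers()].
#' @return Tibble of region counts with a `direction` column.
#' @export
venn_report <- function(markers) {
  cand <- dplyr::filter(markers, .data$candidate)
  if (!nrow(cand)) {
    return(tibble(direction = character(0), full_glucose = logical(0),
                  other_substrates = logical(0), microcosm = logical(0),
                  n = integer(0)))
  }
  cand |>
    dplyr::mutate(direction = ifelse(.data$direction > 0, "positive", "negative")) |>
    dplyr::group_by(
      .data$direction,
      full_glucose = .data$full_pass,
      other_substrates = .data$validated_substrates,
      microcosm = .data$validated_microcosm
    ) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop")
}

#' Run the whole marker pipeline
#'
#' Standardises densities, filters rare features, explores on the exploration
#' subset, validates on the other substrates and community data, and
#' finalizes.
#'
#' @param tree Phylogeny.
#' @param features Count table (taxon, genome_size_mbp, KO columns).
#' @param cue_tables Named list of trait tibbles; the element named
#'   `explore_substrate` is the exploration/full-glucose trait, the others
#'   are validation substrates.
#' @param community Community table (see [validate_microcosm()]), or `NULL`
#'   to skip that route (no candidate can then reach the `final` tier).
#' @param explore_taxa Exploration taxon labels.
#' @param explore_substrate Name of the exploration substrate in
#'   `cue_tables`.
#' @param alpha,min_prevalence,min_substrates,n_perm,seed,lambda_grid,criterion
#'   Stage parameters.
#' @return As [finalize_markers()], plus `tested` (the post-filter feature
#'   count).
#' @export
run_marker_pipeline <- function(tree, features, cue_tables, community,
                                explore_taxa,
                                explore_substrate = "glucose",
                                alpha = 0.05, min_prevalence = 4,
                                min_substrates = 2, n_perm = 999,
                                seed = NULL,
                                lambda_grid = seq(0, 1, by = 0.05),
                                criterion = c("reml", "ml")) {
  criterion <- match.arg(criterion)
  if (!explore_substrate %in% names(cue_tables)) {
    abort_bad_arg("`cue_tables` must contain the exploration substrate.")
  }
  densities <- features |>
    prevalence_filter(min_prevalence = min_prevalence) |>
    standardize_density()
  cue_glu <- cue_tables[[explore_substrate]]
  others <- cue_tables[setdiff(names(cue_tables), explore_substrate)]

  cand <- explore_markers(densities, cue_glu, tree, explore_taxa,
                          alpha = alpha, lambda_grid = lambda_grid,
                          criterion = criterion) |>
    validate_other_substrates(densities, others, tree, alpha = alpha,
                              min_substrates = min_substrates,
                              lambda_grid = lambda_grid,
                              criterion = criterion)
  cand <- if (is.null(community)) {
    dplyr::mutate(cand, microcosm_rho = NA_real_, microcosm_p = NA_real_,
                  validated_microcosm = FALSE)
  } else {
    validate_microcosm(cand, community, alpha = alpha)
  }
  out <- finalize_markers(cand, densities, cue_glu, tree, alpha = alpha,
                          n_perm = n_perm, seed = seed,
                          lambda_method = toupper(criterion))
  out$tested <- nrow(cand)
  out
}

#' PGLS tests of directed trait hypotheses
#'
#' Fits one single-predictor PGLS per (response, predictor) hypothesis pair
#' over the taxa with complete data, the layout of a regression-coefficient
#' table with one hypothesis per column. Hypotheses whose predictor is
#' constant (or that error) are reported with a `skipped` reason rather than
#' failing the batch.
#'
#' @param data Tibble with `taxon` and trait columns (response and predictor
#'   names referenced by `hypotheses`).
#' @param tree Phylogeny.
#' @param hypotheses Tibble with columns `response` and `predictor`.
#' @return Tibble: one row per hypothesis with `slope`, `std.error`, `p`,
#'   `lambda`, `n`, `skipped`.
#' @export
test_a_priori_hypotheses <- function(data, tree, hypotheses) {
  stopifnot(all(c("response", "predictor") %in% names(hypotheses)))
  purrr::pmap(hypotheses, function(response, predictor, ...) {
    base <- tibble(response = response, predictor = predictor,
                   slope = NA_real_, std.error = NA_real_, p = NA_real_,
                   lambda = NA_real_, n = NA_integer_, skipped = NA_character_)
    if (!all(c(response, predictor) %in% names(data))) {
      base$skipped <- "missing column"
      return(base)
    }
    cc <- complete.cases(data[, c(response, predictor)])
    if (length(unique(data[[predictor]][cc])) < 2) {
      base$skipped <- "constant predictor"
      return(base)
    }
    fit <- tryCatch(
      pgls_fit(data, stats::reformulate(predictor, response), tree),
      error = function(e) conditionMessage(e)
    )
    if (is.character(fit)) {
      base$skipped <- fit
      return(base)
    }
    co <- tidy(fit)
    i <- which(co$term != "(Intercept)")[1]
    base$slope <- co$estimate[i]
    base$std.error <- co$std.error[i]
    base$p <- co$p.value[i]
    base$lambda <- fit$lambda
    base$n <- fit$n
    base
  }) |> purrr::list_rbind()
}
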