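#' Run the full synthetic-to-results pipeline
#'
#' Orchestrates an end-to-end reproducible run: simulate growth assays for a
#' set of isolates across substrates and temperatures, estimate and QC-filter
#' CUE, compute Q10 tables, test phylogenetic signal per condition, run
#' leave-one-out tip prediction, and (optionally) the marker screen. Every
#' stage writes a plain-text table into `out_dir` and the manifest records
#' parameters, seeds, file hashes and the package version, so a rerun with
#' the same configuration is bit-identical.
#'
#' The configuration is a nested list (or a YAML file path) with sections
#' `seeds` (named integer seeds per stochastic stage), `growth` (isolates,
#' substrates, temperatures, per-condition simulation parameters), `q10`
#' (`pairs`, `n_boot`), `phylo` (`n_tips`, `n_perm`), and `markers` (set
#' `enabled: true` to run the explore/validate screen).
#'
#' @param config Nested list or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of stage outputs plus the manifest tibble.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cuephylo_run_")) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      abort_bad_arg(sprintf("config file not found: %s", config))
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_defaults(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  seeds <- derive_seeds(cfg$seeds$master, 6)
  message("[cuephylo] simulating growth assays")
  tree <- simulate_tree(cfg$phylo$n_tips, seed = seeds[1],
                        tip_prefix = "iso")
  isolates <- tree$tip.label

  # per-isolate ground-truth physiology: CUE with phylogenetic structure, and
  # a per-degree CUE temperature slope
  base_cue <- 0.45 + 0.35 * stats::plogis(
    as_trait_vector(
      simulate_trait_bm(tree, sigma2 = 1, seed = seeds[2]),
      tree
    )
  )
  temp_slope <- with_seed(seeds[3], rnorm(length(isolates), 0, 0.006))

  cond_seed_pool <- derive_seeds(seeds[4],
                                 length(isolates) * length(cfg$growth$substrates) *
                                   length(cfg$growth$temperatures))
  ci <- 0
  growth <- list()
  for (iso in isolates) {
    for (sub in cfg$growth$substrates) {
      for (tc in cfg$growth$temperatures) {
        ci <- ci + 1
        cue_true <- min(max(base_cue[[iso]] +
                              temp_slope[match(iso, isolates)] * (tc - 20),
                            0.05), 0.95)
        p <- growth_sim_params(
          mu_true = cfg$growth$mu, cue_true = cue_true,
          od_noise_sd = cfg$growth$od_noise_sd,
          co2_noise_sd = cfg$growth$co2_noise_sd,
          temperature_c = tc, seed = cond_seed_pool[ci]
        )
        growth[[ci]] <- simulate_growth_experiment(
          p, n_replicates = cfg$growth$n_replicates,
          isolate = iso, substrate = sub
        )
      }
    }
  }
  growth <- purrr::list_rbind(growth)
  write_growth_csv(growth, file.path(out_dir, "growth_curves.csv"))
  write_tree_newick(tree, file.path(out_dir, "tree.nwk"))

  message("[cuephylo] estimating CUE")
  cue <- estimate_cue(growth)
  cue_qc <- qc_filter(cue)
  readr::write_tsv(cue, file.path(out_dir, "cue_all.tsv"))
  readr::write_tsv(cue_qc, file.path(out_dir, "cue_qc.tsv"))

  message("[cuephylo] Q10 bootstrap")
  pairs <- lapply(cfg$q10$pairs, function(p) as.numeric(p))
  q10_tbl <- q10_table(cue_qc, pairs = pairs, n_boot = cfg$q10$n_boot,
                       seed = seeds[5])
  readr::write_tsv(q10_tbl, file.path(out_dir, "q10.tsv"))

  message("[cuephylo] phylogenetic signal")
  mean_cue <- cue_qc |>
    dplyr::group_by(.data$isolate, .data$substrate, .data$temperature_c) |>
    dplyr::summarise(cue = mean(.data$cue), .groups = "drop")
  sig_rows <- mean_cue |>
    dplyr::group_by(.data$substrate, .data$temperature_c) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 4 || var(d$cue) == 0) return(NULL)
      tr <- setNames(d$cue, d$isolate)
      tips <- intersect(tree$tip.label, names(tr))
      sub_tree <- ape::keep.tip(tree, tips)
      dplyr::bind_cols(key, phylo_signal(sub_tree, tr[tips],
                                         n_perm = cfg$phylo$n_perm,
                                         seed = seeds[6]))
    }) |> purrr::compact() |> purrr::list_rbind()
  readr::write_tsv(sig_rows, file.path(out_dir, "phylo_signal.tsv"))

  message("[cuephylo] leave-one-out tip prediction (glucose)")
  loo <- NULL
  glu <- mean_cue |>
    dplyr::filter(.data$substrate == cfg$growth$substrates[1],
                  .data$temperature_c == cfg$growth$temperatures[1])
  if (nrow(glu) >= 4) {
    tr <- setNames(glu$cue, glu$isolate)
    sub_tree <- ape::keep.tip(tree, intersect(tree$tip.label, names(tr)))
    loo <- predict_tip_loo(sub_tree, tr[sub_tree$tip.label])
    readr::write_tsv(loo$predictions, file.path(out_dir, "tip_predictions.tsv"))
    readr::write_tsv(loo$summary, file.path(out_dir, "tip_prediction_summary.tsv"))
  }

  markers <- NULL
  if (isTRUE(cfg$markers$enabled)) {
    message("[cuephylo] marker screen")
    study <- simulate_marker_study(
      n_taxa = cfg$markers$n_taxa, n_explore = cfg$markers$n_explore,
      n_kos = cfg$markers$n_kos, n_causal = cfg$markers$n_causal,
      seed = cfg$seeds$markers
    )
    markers <- run_marker_pipeline(
      study$tree, study$features, study$cue_tables, study$community,
      study$explore_taxa, alpha = cfg$markers$alpha,
      min_prevalence = cfg$markers$min_prevalence,
      n_perm = cfg$phylo$n_perm, seed = cfg$seeds$markers
    )
    readr::write_tsv(markers$markers, file.path(out_dir, "markers.tsv"))
    readr::write_tsv(markers$report, file.path(out_dir, "marker_venn.tsv"))
  }

  manifest <- build_manifest(out_dir, cfg)
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"))

  invisible(list(
    out_dir = out_dir, tree = tree, growth = growth, cue = cue,
    cue_qc = cue_qc, q10 = q10_tbl, signal = sig_rows, loo = loo,
    markers = markers, manifest = manifest, config = cfg
  ))
}

pipeline_defaults <- function(config) {
  defaults <- list(
    seeds = list(master = 1L, markers = 1L),
    growth = list(
      substrates = c("glucose", "pyruvate"),
      temperatures = c(15, 20, 25),
      n_replicates = 3, mu = 0.3, od_noise_sd = 0.01, co2_noise_sd = 5
    ),
    q10 = list(pairs = list(c(15, 20), c(20, 25), c(15, 25)), n_boot = 500),
    phylo = list(n_tips = 16, n_perm = 499),
    markers = list(enabled = FALSE, n_taxa = 40, n_explore = 20,
                   n_kos = 200, n_causal = 5, alpha = 0.05,
                   min_prevalence = 4)
  )
  utils::modifyList(defaults, config %||% list())
}

build_manifest <- function(out_dir, cfg) {
  files <- sort(list.files(out_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.tsv")
  tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    package_version = as.character(utils::packageVersion("cuephylo")),
    master_seed = cfg$seeds$master
  )
}

#' Summarise a completed pipeline run into report tables
#'
#' Reads the stage outputs written by [run_pipeline()] and reshapes them into
#' the familiar report layouts without recomputing anything: a phylogenetic
#' signal grid (substrate x temperature with K and lambda and significance
#' stars), a Q10 grid, and the marker Venn summary when present.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @return A list of tibbles: `signal_table`, `q10_table`, and optionally
#'   `marker_venn`. Also written as `report_*.tsv` into `run_dir`.
#' @export
make_report <- function(run_dir) {
  need <- c("phylo_signal.tsv", "q10.tsv")
  missing_files <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing_files)) {
    abort_bad_arg(paste0("missing stage outputs: ",
                         paste(missing_files, collapse = ", ")))
  }
  stars <- function(p) {
    dplyr::case_when(
      p <= 0.001 ~ "***", p <= 0.01 ~ "**", p <= 0.05 ~ "*",
      p <= 0.1 ~ ".", TRUE ~ ""
    )
  }
  sig <- readr::read_tsv(file.path(run_dir, "phylo_signal.tsv"),
                         show_col_types = FALSE) |>
    dplyr::mutate(
      k_label = sprintf("%.2f%s", .data$k, stars(.data$k_p)),
      lambda_label = sprintf("%.2f%s", .data$lambda, stars(.data$lambda_p))
    ) |>
    dplyr::select("substrate", "temperature_c", "k_label", "lambda_label")

  q10_raw <- readr::read_tsv(file.path(run_dir, "q10.tsv"),
                             show_col_types = FALSE)
  q10_grid <- q10_raw |>
    dplyr::mutate(
      range = sprintf("%g-%g", .data$t_low, .data$t_high),
      label = sprintf("%.2f [%.2f, %.2f]%s", .data$q10, .data$ci_low,
                      .data$ci_high,
                      ifelse(!is.na(.data$sensitive) & .data$sensitive, "*", ""))
    ) |>
    dplyr::select("isolate", "substrate", "range", "label") |>
    tidyr::pivot_wider(names_from = "range", values_from = "label")

  out <- list(signal_table = sig, q10_table = q10_grid)
  readr::write_tsv(sig, file.path(run_dir, "report_signal.tsv"))
  readr::write_tsv(q10_grid, file.path(run_dir, "report_q10.tsv"))

  venn_path <- file.path(run_dir, "marker_venn.tsv")
  if (file.exists(venn_path)) {
    out$marker_venn <- readr::read_tsv(venn_path, show_col_types = FALSE)
  }
  out
}
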