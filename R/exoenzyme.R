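# Theoretical carbon cost of extracellular enzyme production.
#
# Producing a secreted protein costs ATP twice: synthesising each amino acid
# de novo and polymerising the chain (4.2 ATP per peptide bond). With 26 ATP
# produced per 6 glucose carbons respired, every ATP spent maps to 6/26 of a
# carbon atom respired, so each protein has a theoretical carbon assimilation
# efficiency n_C / (n_C + ATP * 6/26): the fraction of carbon flowing into
# the protein rather than out as CO2 while paying for it.

# carbon atoms per residue as incorporated in a peptide (standard chemistry)
AA_CARBONS <- c(
  A = 3, R = 6, N = 4, D = 4, C = 3, E = 5, Q = 5, G = 2, H = 6, I = 6,
  L = 6, K = 6, M = 5, F = 9, P = 5, S = 3, T = 4, W = 11, Y = 9, V = 5
)

#' Stoichiometric constants of the protein cost model
#'
#' @param atp_per_bond ATP consumed per peptide bond formed.
#' @param atp_per_glucose ATP produced per `carbons_per_glucose` glucose
#'   carbons respired.
#' @param carbons_per_glucose Carbon atoms per glucose molecule.
#' @return A validated list of class `cost_parameters`.
#' @export
cost_parameters <- function(atp_per_bond = 4.2, atp_per_glucose = 26,
                            carbons_per_glucose = 6) {
  check_number(atp_per_bond, "atp_per_bond", min = 0, allow_min = FALSE)
  check_number(atp_per_glucose, "atp_per_glucose", min = 0, allow_min = FALSE)
  check_number(carbons_per_glucose, "carbons_per_glucose", min = 0,
               allow_min = FALSE)
  structure(
    list(atp_per_bond = atp_per_bond, atp_per_glucose = atp_per_glucose,
         carbons_per_glucose = carbons_per_glucose),
    class = "cost_parameters"
  )
}

#' Read an amino acid cost table
#'
#' The table must have columns `residue` (one-letter code), `atp_cost` (ATP
#' per molecule synthesised de novo) and `n_carbon` (carbon atoms per
#' residue), with all 20 standard residues present. A synthetic template with
#' plausible cost magnitudes ships with the package
#' (`system.file("extdata", "amino_acid_costs_synthetic.tsv", package =
#' "cuephylo")`); substitute measured biosynthesis costs for real analyses.
#'
#' @param path TSV file path; defaults to the bundled synthetic table.
#' @return Tibble with `residue`, `atp_cost`, `n_carbon`.
#' @export
read_cost_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "amino_acid_costs_synthetic.tsv",
                                package = "cuephylo")
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         comment = "#")
  validate_cost_table(tbl)
}

validate_cost_table <- function(tbl) {
  stopifnot(all(c("residue", "atp_cost", "n_carbon") %in% names(tbl)))
  missing_res <- setdiff(names(AA_CARBONS), tbl$residue)
  if (length(missing_res)) {
    abort_bad_arg(paste0("cost table is missing residues: ",
                         paste(missing_res, collapse = ", ")))
  }
  if (any(tbl$atp_cost < 0)) abort_bad_arg("negative ATP costs.")
  as_tibble(tbl)
}

split_residues <- function(protein_seq, table, on_unknown = c("error", "skip")) {
  on_unknown <- match.arg(on_unknown)
  if (!nzchar(protein_seq)) abort_bad_arg("empty protein sequence.")
  res <- strsplit(toupper(protein_seq), "")[[1]]
  res <- res[res != "*"] # tolerate a trailing stop
  known <- res %in% table$residue
  if (any(!known)) {
    if (on_unknown == "error") {
      abort_bad_arg(paste0("unknown residue symbol(s): ",
                           paste(unique(res[!known]), collapse = ", ")))
    }
    warning(sprintf("skipping %d unknown residue(s).", sum(!known)))
    res <- res[known]
  }
  if (!length(res)) abort_bad_arg("no known residues in sequence.")
  res
}

#' Total carbon atoms in a protein
#'
#' @param protein_seq One-letter amino acid string.
#' @param table Cost table (see [read_cost_table()]); only `n_carbon` is used.
#' @param on_unknown `"error"` (default) or `"skip"` unknown residue symbols.
#' @return Total carbon atoms.
#' @export
residue_carbons <- function(protein_seq, table = read_cost_table(),
                            on_unknown = c("error", "skip")) {
  res <- split_residues(protein_seq, table, on_unknown)
  sum(table$n_carbon[match(res, table$residue)])
}

#' Total ATP cost of synthesising a protein
#'
#' Sum of per-residue de novo biosynthesis costs plus `atp_per_bond` per
#' peptide bond (`length - 1` bonds).
#'
#' @inheritParams residue_carbons
#' @param params [cost_parameters()].
#' @return ATP per protein molecule.
#' @export
protein_atp_cost <- function(protein_seq, table = read_cost_table(),
                             params = cost_parameters(),
                             on_unknown = c("error", "skip")) {
  res <- split_residues(protein_seq, table, on_unknown)
  sum(table$atp_cost[match(res, table$residue)]) +
    params$atp_per_bond * (length(res) - 1)
}

#' Theoretical carbon assimilation efficiency of producing one protein
#'
#' Converts the protein's total ATP cost to respired carbon
#' (`ATP * carbons_per_glucose / atp_per_glucose`) and returns
#' `n_C / (n_C + C_respired)`.
#'
#' @inheritParams protein_atp_cost
#' @return CUE of producing the protein, in (0, 1].
#' @export
protein_cue <- function(protein_seq, table = read_cost_table(),
                        params = cost_parameters(),
                        on_unknown = c("error", "skip")) {
  res <- split_residues(protein_seq, table, on_unknown)
  n_carbon <- sum(table$n_carbon[match(res, table$residue)])
  atp <- sum(table$atp_cost[match(res, table$residue)]) +
    params$atp_per_bond * (length(res) - 1)
  c_respired <- atp * params$carbons_per_glucose / params$atp_per_glucose
  n_carbon / (n_carbon + c_respired)
}

# codon -> amino acid map for the standard genetic code, stops excluded
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  tibble(codon = names(gc), aa = unname(gc)) |>
    dplyr::filter(.data$aa != "*")
}

count_codons <- function(cds) {
  ct <- codon_table()
  counts <- setNames(numeric(nrow(ct)), ct$codon)
  for (s in cds) {
    s <- toupper(s)
    if (nchar(s) %% 3 != 0) abort_bad_arg("CDS length not divisible by 3.")
    codons <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
    tab <- table(codons)
    hit <- intersect(names(tab), names(counts))
    counts[hit] <- counts[hit] + tab[hit]
  }
  counts
}

#' Codon-bias expression weights from a highly expressed reference set
#'
#' Computes per-codon relative adaptiveness `w` from the codon usage of a
#' reference gene set (within each synonymous family, frequency divided by
#' the family's maximum frequency; unobserved codons are floored at 0.5
#' counts), the codon adaptation index (CAI) of each gene as the geometric
#' mean of `w` over its codons (single-codon families Met and Trp and stop
#' codons excluded), and expression weights proportional to CAI, normalised
#' to sum to one over the gene set.
#'
#' @param cds Named character vector (or `Biostrings::DNAStringSet`) of
#'   coding sequences; lengths must be multiples of 3. Internal stop codons
#'   are skipped with a warning.
#' @param reference_cds Reference coding sequences (e.g. ribosomal protein
#'   genes) defining the "highly expressed" codon usage.
#' @return A list: `w` (tibble `codon`, `aa`, `w`), `cai` (tibble `id`,
#'   `cai`, `weight`).
#' @export
codon_bias_weights <- function(cds, reference_cds) {
  cds <- as_cds_character(cds)
  reference_cds <- as_cds_character(reference_cds)
  if (!length(reference_cds)) abort_bad_arg("empty reference CDS set.")
  ct <- codon_table()
  ref_counts <- count_codons(reference_cds)
  ref_counts[ref_counts == 0] <- 0.5
  aa_of <- ct$aa[match(names(ref_counts), ct$codon)]
  fam_max <- tapply(ref_counts, aa_of, max)
  w <- setNames(as.numeric(ref_counts) / as.numeric(fam_max[aa_of]),
                names(ref_counts))

  fam_size <- table(ct$aa)
  informative <- ct$codon[fam_size[ct$aa] > 1]

  cai <- vapply(seq_along(cds), function(i) {
    s <- toupper(cds[[i]])
    if (nchar(s) %% 3 != 0) abort_bad_arg("CDS length not divisible by 3.")
    codons <- substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
    is_stop <- !codons %in% ct$codon
    if (any(is_stop[-length(codons)])) {
      warning(sprintf("internal stop codon(s) in CDS %d; skipped.", i))
    }
    codons <- codons[codons %in% informative]
    if (!length(codons)) return(NA_real_)
    exp(mean(log(w[codons])))
  }, numeric(1))

  weights <- cai / sum(cai, na.rm = TRUE)
  list(
    w = tibble(codon = names(w), aa = ct$aa[match(names(w), ct$codon)],
               w = unname(w)),
    cai = tibble(id = names(cds) %||% as.character(seq_along(cds)),
                 cai = cai, weight = weights)
  )
}

as_cds_character <- function(x) {
  if (inherits(x, "DNAStringSet") || inherits(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else {
    abort_bad_arg("CDS input must be a character vector or DNAStringSet.")
  }
}

#' Expression-weighted organism-level exoenzyme production CUE
#'
#' Computes the per-protein theoretical production CUE for a set of
#' (pre-flagged) extracellular enzymes and averages them weighted by
#' codon-bias-predicted relative expression.
#'
#' @param proteins Named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param cds Matching named coding sequences (ids must agree with
#'   `proteins`).
#' @param table Amino acid cost table.
#' @param params [cost_parameters()].
#' @param reference_cds Highly expressed reference gene set for
#'   [codon_bias_weights()].
#' @return A list: `per_protein` (tibble: `id`, `n_carbon`, `atp_total`,
#'   `cue_protein`, `cai`, `weight`) and `organism` (one-row tibble with the
#'   weighted mean CUE).
#' @export
organism_exoenzyme_cue <- function(proteins, cds, table = read_cost_table(),
                                   params = cost_parameters(),
                                   reference_cds = NULL) {
  proteins <- as_protein_character(proteins)
  cds <- as_cds_character(cds)
  ids <- names(proteins) %||% as.character(seq_along(proteins))
  names(proteins) <- ids
  if (!setequal(ids, names(cds) %||% as.character(seq_along(cds)))) {
    abort_bad_arg("protein and CDS ids do not match.")
  }
  cds <- cds[ids]

  per <- purrr::map(ids, function(id) {
    s <- proteins[[id]]
    tibble(
      id = id,
      n_carbon = residue_carbons(s, table),
      atp_total = protein_atp_cost(s, table, params),
      cue_protein = protein_cue(s, table, params)
    )
  }) |> purrr::list_rbind()

  if (is.null(reference_cds)) {
    # no expression model: uniform weights
    per$cai <- NA_real_
    per$weight <- 1 / nrow(per)
  } else {
    cb <- codon_bias_weights(cds, reference_cds)
    per$cai <- cb$cai$cai[match(per$id, cb$cai$id)]
    per$weight <- cb$cai$weight[match(per$id, cb$cai$id)]
  }
  organism <- tibble(
    n_proteins = nrow(per),
    cue_weighted = sum(per$cue_protein * per$weight) / sum(per$weight),
    cue_unweighted = mean(per$cue_protein)
  )
  list(per_protein = per, organism = organism)
}

as_protein_character <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "XStringSet")) {
    setNames(as.character(x), names(x))
  } else if (is.character(x)) {
    x
  } else {
    abort_bad_arg("protein input must be a character vector or AAStringSet.")
  }
}

#' Flag putative extracellular enzymes by annotation keywords
#'
#' A string-matching convenience over an annotation table: marks proteins
#' whose functional annotation matches any of the classic secreted-enzyme
#' keyword stems (protease/proteinase/peptidase/phosphatase/phospholipase by
#' default, matched case-insensitively anywhere in the annotation).
#'
#' @param annotations Tibble with columns `id` and `annotation`.
#' @param patterns Character vector of regular expressions.
#' @return The tibble with a logical `extracellular` column.
#' @export
flag_extracellular <- function(annotations,
                               patterns = c("rotease", "roteinase",
                                            "eptidase", "hosphatase",
                                            "hospholipase")) {
  stopifnot(all(c("id", "annotation") %in% names(annotations)))
  hit <- Reduce(`|`, lapply(patterns, function(p) {
    stringr::str_detect(annotations$annotation, stringr::regex(p, ignore_case = TRUE))
  }))
  dplyr::mutate(annotations, extracellular = hit)
}
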