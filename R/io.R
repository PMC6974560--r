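# Plain-text readers/writers for the pipeline's interchange formats:
# growth assays as CSV, traits and feature tables as TSV, trees as Newick,
# sequences as FASTA.

#' Read or write a tidy growth-assay table
#'
#' Columns: `isolate`, `substrate`, `temperature_c`, `replicate`, `time_h`,
#' `od600`, `co2_ppm`.
#'
#' @param path File path.
#' @return A tibble (reader) or the input, invisibly (writer).
#' @export
read_growth_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("isolate", "substrate", "temperature_c", "replicate",
            "time_h", "od600", "co2_ppm")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort_bad_arg(paste0("growth CSV is missing columns: ",
                         paste(missing_cols, collapse = ", ")))
  }
  d
}

#' @rdname read_growth_csv
#' @param data Growth table to write.
#' @export
write_growth_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}

#' Read or write a taxon-by-feature TSV
#'
#' First column `taxon`, remaining columns numeric features (typically KO
#' counts plus `genome_size_mbp`).
#'
#' @param path File path.
#' @export
read_feature_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(d)[1] != "taxon") abort_bad_arg("first column must be `taxon`.")
  d
}

#' @rdname read_feature_tsv
#' @param data Feature table to write.
#' @export
write_feature_tsv <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(data)
}

#' Read or write a (taxon, value) trait TSV
#'
#' @param path File path.
#' @export
read_trait_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("taxon", "value") %in% names(d))) {
    abort_bad_arg("trait TSV needs `taxon` and `value` columns.")
  }
  d
}

#' @rdname read_trait_tsv
#' @param trait Trait tibble or named vector to write.
#' @export
write_trait_tsv <- function(trait, path) {
  if (!is.data.frame(trait)) trait <- trait_tibble(as_trait_vector(trait))
  readr::write_tsv(trait, path)
  invisible(trait)
}

#' Read or write a Newick tree
#'
#' Thin wrappers over `ape` with existence checks.
#'
#' @param path File path.
#' @export
read_tree_newick <- function(path) {
  if (!file.exists(path)) abort_bad_arg(sprintf("tree file not found: %s", path))
  ape::read.tree(path)
}

#' @rdname read_tree_newick
#' @param tree `ape::phylo` object to write.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' Read or write FASTA sequences
#'
#' @param path File path.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences to write.
#' @export
write_fasta <- function(seqs, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(seqs)
}
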