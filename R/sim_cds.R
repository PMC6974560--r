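#' Simulate coding sequences with controlled codon bias
#'
#' Draws random protein sequences and back-translates them choosing, for each
#' amino acid, its preferred codon with probability
#' `codon_bias_strength + (1 - codon_bias_strength) / family_size` and any
#' synonymous codon uniformly otherwise: strength 0 gives uniform synonymous
#' usage, strength 1 always the preferred codon. Preferred codons and
#' reference frequencies default to a built-in biased usage table
#' (frequencies proportional to `0.55^rank` within each family, deterministic
#' codon order), or can be supplied.
#'
#' @param n_genes Number of genes.
#' @param codon_bias_strength Bias strength in `[0, 1]`.
#' @param reference_codon_freqs Optional named numeric vector over the 61
#'   sense codons; frequencies must be positive and are normalised within
#'   each synonymous family. The family maximum defines the preferred codon.
#' @param length_aa_range Range of protein lengths (residues).
#' @param seed Optional RNG seed.
#' @return A list: `cds` and `protein` (named character vectors, ids
#'   `g1..gN`; the proteins are the standard-code translations) and
#'   `reference_codon_freqs` used.
#' @export
simulate_cds <- function(n_genes, codon_bias_strength = 0.5,
                         reference_codon_freqs = NULL,
                         length_aa_range = c(80, 300), seed = NULL) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  check_number(codon_bias_strength, "codon_bias_strength", min = 0, max = 1)
  ct <- codon_table()
  if (is.null(reference_codon_freqs)) {
    reference_codon_freqs <- default_reference_freqs()
  }
  if (!all(ct$codon %in% names(reference_codon_freqs))) {
    abort_bad_arg("`reference_codon_freqs` must cover all 61 sense codons.")
  }
  if (any(reference_codon_freqs[ct$codon] <= 0)) {
    abort_bad_arg("reference codon frequencies must be positive.")
  }

  fam <- split(ct$codon, ct$aa)
  aas <- names(fam)
  s <- codon_bias_strength

  with_seed(seed, {
    lens <- sample(length_aa_range[1]:length_aa_range[2], n_genes,
                   replace = TRUE)
    cds <- character(n_genes)
    prot <- character(n_genes)
    for (g in seq_len(n_genes)) {
      aa_seq <- sample(aas, lens[g], replace = TRUE)
      codons <- vapply(aa_seq, function(a) {
        syn <- fam[[a]]
        k <- length(syn)
        pref <- syn[which.max(reference_codon_freqs[syn])]
        probs <- rep((1 - s) / k, k)
        probs[match(pref, syn)] <- probs[match(pref, syn)] + s
        sample(syn, 1, prob = probs)
      }, character(1))
      cds[g] <- paste(codons, collapse = "")
      prot[g] <- paste(aa_seq, collapse = "")
    }
    names(cds) <- names(prot) <- sprintf("g%d", seq_len(n_genes))
    list(cds = cds, protein = prot,
         reference_codon_freqs = reference_codon_freqs)
  })
}

# built-in mildly biased reference usage: within each synonymous family the
# codons (in alphabetical order) get frequencies proportional to 0.55^rank
default_reference_freqs <- function() {
  ct <- codon_table()
  freqs <- numeric(nrow(ct))
  names(freqs) <- ct$codon
  for (a in unique(ct$aa)) {
    syn <- sort(ct$codon[ct$aa == a])
    p <- 0.55^(seq_along(syn) - 1)
    freqs[syn] <- p / sum(p)
  }
  freqs
}

#' Translate coding sequences with the standard genetic code
#'
#' @param cds Named character vector or `Biostrings::DNAStringSet`.
#' @return Named character vector of protein sequences.
#' @export
translate_cds <- function(cds) {
  cds <- as_cds_character(cds)
  out <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds), no.init.codon = TRUE
  ))
  setNames(out, names(cds))
}
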