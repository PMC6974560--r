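# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_bad_arg <- function(msg) stop(msg, call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf,
                         allow_min = TRUE, allow_max = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_min) x >= min else x > min
  hi_ok <- if (allow_max) x <= max else x < max
  if (!lo_ok || !hi_ok) {
    abort_bad_arg(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).",
      name, if (allow_min) "[" else "(", format(min),
      format(max), if (allow_max) "]" else ")", x
    ))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < min) {
    abort_bad_arg(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

# Coerce a trait given as a named vector or (taxon, value) tibble to a named
# numeric vector, optionally aligned to tree tip labels.
as_trait_vector <- function(trait, tree = NULL, value_col = "value") {
  if (is.data.frame(trait)) {
    if (!all(c("taxon", value_col) %in% names(trait))) {
      abort_bad_arg("trait data frame needs columns `taxon` and `value`.")
    }
    out <- setNames(as.numeric(trait[[value_col]]), trait[["taxon"]])
  } else if (is.numeric(trait) && !is.null(names(trait))) {
    out <- trait
  } else {
    abort_bad_arg("trait must be a named numeric vector or (taxon, value) tibble.")
  }
  if (anyDuplicated(names(out))) abort_bad_arg("duplicated taxon labels in trait.")
  if (!is.null(tree)) {
    keep <- intersect(tree$tip.label, names(out))
    if (length(keep) < length(tree$tip.label)) {
      abort_bad_arg("trait is missing values for some tree tips.")
    }
    out <- out[tree$tip.label]
  }
  out[is.finite(out) | is.na(out)]
}

trait_tibble <- function(x) {
  tibble(taxon = names(x), value = unname(as.numeric(x)))
}

# Deterministic child RNG seeds derived from one parent seed; kept below
# 2^31 so they are valid R integer seeds.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Evaluate `expr` under a local RNG stream (seed may be NULL for "use current").
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}
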