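# Shared fixtures and independent oracles, built in code.

# four-tip star tree with unit branches
star_tree4 <- function() {
  ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
}

# balanced four-tip tree with printed branch lengths:
# ((a:1,b:1):2,(c:2,d:2):1); depths: all 3 (ultrametric)
balanced_tree4 <- function() {
  ape::read.tree(text = "((a:1,b:1):2,(c:2,d:2):1);")
}

# two deep clades, shallow within-clade divergences
two_clade_tree <- function(n_per = 4) {
  left <- paste0("(", paste(sprintf("l%d:0.2", seq_len(n_per)), collapse = ","), "):4.8")
  right <- paste0("(", paste(sprintf("r%d:0.2", seq_len(n_per)), collapse = ","), "):4.8")
  ape::read.tree(text = paste0("(", left, ",", right, ");"))
}

# exhaustive, independent window-search oracle using lm()
window_oracle <- function(time_h, ln_biomass, min_pts = 3, max_pts = 10) {
  n <- length(time_h)
  best <- NULL
  for (start in seq_len(n)) {
    for (end in seq_len(n)) {
      len <- end - start + 1
      if (len < min_pts || len > max_pts || end > n) next
      sl <- unname(coef(lm(ln_biomass[start:end] ~ time_h[start:end]))[2])
      better <- is.null(best) ||
        sl > best$slope + 1e-9 * max(1, abs(best$slope)) ||
        (abs(sl - best$slope) <= 1e-9 * max(1, abs(best$slope)) &&
           (len > best$n || (len == best$n && start < best$start)))
      if (better) best <- list(start = start, end = end, n = len, slope = sl)
    }
  }
  best
}

# noiseless growth table for a given truth
noiseless_growth <- function(mu = 0.3, cue = 0.6, ...) {
  p <- growth_sim_params(mu_true = mu, cue_true = cue,
                         od_noise_sd = 0, co2_noise_sd = 0, seed = 1, ...)
  simulate_growth_experiment(p, n_replicates = 1)
}

# brute-force all-pairs Q10 oracle
q10_pairs_oracle <- function(lo, hi, t_lo, t_hi) {
  vals <- c()
  for (a in lo) for (b in hi) vals <- c(vals, (b / a)^(10 / (t_hi - t_lo)))
  vals
}
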