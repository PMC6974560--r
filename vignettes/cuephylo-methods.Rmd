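---
title: "Methods: carbon use efficiency, its temperature response, and its genomic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon use efficiency, its temperature response, and its genomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cuephylo implements an analysis chain for measuring bacterial carbon use
efficiency (CUE) in batch culture, quantifying how CUE responds to
temperature, and asking whether CUE and its temperature response can be read
off a genome: phylogenetic signal tests, phylogenetically corrected
regression against genome features, an explore/validate marker screen, and a
theoretical cost model for extracellular enzyme production. A synthetic-data
module generates every input with known ground truth, so each stage's
operating characteristics are measured, not assumed. This vignette explains
the models, the tunable parameters, the numerical choices, and what the
synthetic tests do and do not establish about real data.

## CUE from growth curves

A replicate is a time series of optical density (OD600) and headspace CO2
(ppm) for one isolate, substrate and temperature. During balanced exponential
growth, biomass carbon obeys $B(t) = B_0 e^{\mu t}$ and respiration is
proportional to biomass, $dC/dt = R\,B(t)$, where $\mu$ (h$^{-1}$) is the
intrinsic growth rate and $R$ (h$^{-1}$) the mass-specific respiration rate.
Carbon use efficiency is the growth fraction of the processed carbon,

$$\mathrm{CUE} = \frac{\mu}{\mu + R}.$$

The estimation steps:

1. **Exponential window.** `find_exponential_window()` scans every
   contiguous run of 3 to 10 time points and keeps the one maximising the
   least-squares slope of $\ln B$ against time. Ties within a relative
   tolerance of $10^{-9}$ go to the longer window, then the earlier start, so
   a perfectly log-linear stretch yields the longest admissible window. The
   bounds (3, 10) and the maximisation rule are the assay's definition of
   "the exponential phase"; the tie-break is ours, chosen for determinism.
   With a maximum-slope rule, very slow growers (μ near 0.01 h$^{-1}$) need
   reads spread over a long enough assay that the true slope dominates read
   noise; the simulators used in the tests spread 24 reads over
   $\max(24, 4/\mu)$ hours, the way a bench protocol follows slow isolates
   for longer.
2. **Units.** OD converts to biomass carbon linearly
   (`biomass_per_od`, default 130 µg C OD$^{-1}$ ml$^{-1}$, times the
   culture volume). The printed unit of this classic conversion factor is
   ambiguous in parts of the literature; the number is configurable, and CUE
   itself requires only that biomass carbon and respired carbon share a mass
   unit — rescaling both jointly leaves CUE unchanged (a tested invariant).
   Headspace ppm converts to µg CO2-C by the ideal gas law at the assay
   temperature, baseline (first read) subtracted, assuming instantaneous
   solution/headspace equilibration (cultures are vortexed before reading).
3. **Rates.** $\mu$ is the OLS slope of $\ln B$ over the window, with the
   single-regressor F test ($F = t^2$, $n-2$ df). The default $R$ estimator
   uses the exact identity that under exponential growth cumulative CO2-C is
   linear in biomass with slope $R/\mu$; regressing CO2-C on $B$ and
   multiplying by $\hat\mu$ is exact on noiseless curves and insensitive to
   read-time jitter. A per-interval estimator (mean of
   $\Delta C/\Delta t$ over geometric-mean biomass) is available as
   `method = "interval"` for sensitivity analysis; the two agree within 1%
   on clean data.
4. **QC.** Replicates whose growth or respiration slope does not differ from
   zero (F test $p > 0.05$) are discarded; conditions retaining fewer than
   two replicates are dropped entirely (`qc_filter()`).

Under the synthetic generator's default read noise (multiplicative
log-normal OD noise, sd 0.01; additive CO2 noise), the acceptance suite
measures a mean absolute CUE error near 0.01 over the observed physiological
range, and exact recovery (to numerical precision) on noiseless curves.

## Temperature sensitivity (Q10)

$Q_{10} = (\mathrm{CUE}_{high}/\mathrm{CUE}_{low})^{10/\Delta T}$ is the
factor by which CUE changes per 10 °C. Because replicate pairings across
temperatures are arbitrary (concurrent cultivation across all conditions
rarely succeeds), `q10_all_pairs()` computes all cross-pairs; the standard
error is the standard deviation of the pairwise values over $\sqrt{n_{pairs}}$.
Since $Q_{10}$ is nonlinear in the two CUE values, the point estimate is the
$Q_{10}$ of the replicate means, not the mean of pairwise $Q_{10}$s; both are
reported.

`bootstrap_q10()` resamples replicates with replacement within each
temperature and reports the percentile 95% interval of the mean-based
$Q_{10}$; a condition is "temperature sensitive" when the interval excludes
1. The percentile method (rather than BCa) was chosen for its simplicity at
small replicate counts. **Known limitation, measured by the acceptance
suite:** at 3 replicates per temperature the percentile interval is
substantially anticonservative — measured coverage ≈ 0.79 against a nominal
0.95, and ≈ 19% of truly insensitive conditions get flagged sensitive. This
is structural: with $n=3$ the bootstrap distribution has only 10 distinct
resamples per side and its spread underestimates the sampling error; even
the expanded-percentile correction reaches only ≈ 0.88. Interval
classifications at this replication level should be read as descriptive, and
"insensitive" fractions derived from them as lower bounds.

## Phylogenetic signal and comparative regression

All comparative statistics run on the Brownian covariance $V$ of a rooted
tree ($V_{ij}$ = shared root-to-MRCA branch length; `vcv_matrix()`), with
Pagel's transform $V_\lambda$ multiplying off-diagonals by $\lambda$. The
transform is applied in covariance space — the standard definition — rather
than by literally rescaling terminal branches; for ultrametric trees the two
coincide. $\lambda$ is capped at 1 (for ultrametric trees the feasible
maximum), and for ultrametric trees
$V_\lambda = \lambda V + (1-\lambda) T I$ shares $V$'s eigenvectors, so one
eigendecomposition per tree makes each likelihood evaluation $O(n)$ after
rotating the data once; non-ultrametric input falls back to a Cholesky per
evaluation (the two routes agree to $10^{-8}$, a tested invariant).

* **Blomberg's K** (`blomberg_k()`): the observed ratio of the mean squared
  deviation from the GLS phylogenetic mean to its $V^{-1}$-weighted
  counterpart, divided by the Brownian expectation
  $(\mathrm{tr}V - n/\mathbf{1}'V^{-1}\mathbf{1})/(n-1)$. $K=1$ under
  Brownian motion (mean K over 500 Brownian simulations on a 32-tip tree
  falls in [0.9, 1.1] in the acceptance suite). Significance is a one-sided
  permutation test (999 shuffles, add-one smoothing) on the
  phylogenetically weighted mean squared error — signal means relatives are
  closer than random arrangements.
* **Pagel's λ** (`pagel_lambda_ml()`): profile maximum likelihood over
  $\lambda \in [0, 1]$ (mean and scale profiled analytically; coarse grid
  then bounded refinement, tolerance $10^{-8}$, to dodge local optima), with
  a likelihood-ratio test against $\lambda = 0$ on $\chi^2_1$ — the
  convention of the common comparative-methods tools, anticonservative at
  the boundary; $\hat\lambda = 0$ reports $p = 1$.
* **Brownian reference intervals** (`bm_signal_ci()`): simulate Brownian
  traits on the fixed tree and report the 2.5–97.5% quantiles of $K$ and
  $\hat\lambda$, the band a Brownian trait would occupy on this tree.
* **PGLS** (`pgls_fit()`): GLS with residual covariance
  $\sigma^2 V_\lambda$, λ profiled by ML (default) or REML, or fixed.
  Coefficient tests use the unbiased residual variance with $n-p$ df. With
  $\lambda = 0$ the fit reproduces OLS to $10^{-10}$ (tested); fixed-λ fits
  match `nlme::gls` with a Pagel correlation exactly.
* **Unsampled-tip prediction** (`predict_tip_loo()`): leave each tip out and
  predict it as the Brownian/GLS conditional expectation
  $a + V_{io}V_{oo}^{-1}(y_o - a\mathbf{1})$ on the λ-rescaled covariance
  (λ fit on the full data), which is mathematically identical to re-rooting
  the pruned tree at the attachment point and taking the ancestral estimate
  there — asserted against an independent re-rooting oracle to $10^{-8}$.
  Reported alongside: Spearman correlations of observed vs predicted values
  and of the signed and absolute estimation error vs patristic distance to
  the nearest remaining tip (the error–distance question is emitted both
  ways because either convention appears in practice).

### ML vs REML in the marker screen

Profiling λ by ML per model is the historical choice of the comparative
tools this design follows. Measured at screen sample sizes (n = 20–40), the
ML $\hat\lambda$ is biased low (median 0.19 against a truth of 0.31 at
n = 40), and the resulting slope t-tests are anticonservative. The
per-feature screen therefore defaults to REML profiling — the standard
small-sample treatment of variance components — which removes most of the
λ bias; `criterion = "ml"` reproduces the plain ML behaviour for strict
replication. Residual anticonservatism remains (measured null hit rate
≈ 0.08 at α = 0.05 with a 20-taxon exploration set) because selecting λ
per feature is itself a fitted quantity; with λ fixed at its true value the
test is exactly calibrated (measured 0.050). This is a property of the
method class, and the package reports it rather than hiding it.

## The explore/validate marker screen

`run_marker_pipeline()` mirrors a two-stage comparative-genomics design:

1. counts are genome-size standardised (per Mbp) and rare functions
   (present in fewer than `min_prevalence = 4` genomes — "a few", made
   explicit and configurable) are removed before testing;
2. **explore**: per-feature PGLS of CUE on density over a designated
   exploration taxon subset, candidates at raw α = 0.05 (no multiplicity
   correction by default — the design's false-discovery control is the
   validation conjunction below; a Benjamini–Hochberg option exists);
3. **validate**: candidates must show a same-direction significant slope in
   the full (exploration + validation) glucose data, in at least 2 of 3
   other substrates, and/or a same-direction significant Spearman
   correlation with community CUE across microcosms;
4. **residual check**: confirmed candidates' full-data fits must leave no
   phylogenetic signal in the *normalized* (phylogeny-corrected) residuals —
   neither the K permutation test nor the λ LRT significant at 0.05.
   Response-scale residuals of a λ-model retain structure by construction,
   so the check whitens by the fitted covariance first; the qualitative
   "examine residual plots" step of the original design is replaced by these
   two explicit tests.

Two validation tiers are reported. `validated_any` requires the substrate
route *or* the community route — the tier a supplementary marker table would
list. `final` requires *both* routes ("uniformly validated") — under a
complete null this conjunction makes a false finalized marker vanishingly
rare (no finalized markers in ≥ 95% of null runs in the acceptance suite),
which is the quantitative content of the observation that candidate markers
almost never survive validation by independent data sets. The Venn-style
report (`venn_report()`) partitions candidates by their membership in the
three validating data sets, split by direction of association.

## Exoenzyme production cost

Producing a secreted protein costs ATP for amino acid biosynthesis (a
per-residue cost table; the bundled
`inst/extdata/amino_acid_costs_synthetic.tsv` is a synthetic template with
plausible magnitudes — substitute measured values) plus 4.2 ATP per peptide
bond. With 26 ATP produced per 6 glucose carbons respired, the theoretical
production efficiency of a protein with $n_C$ carbons and total cost $A$ ATP
is $n_C / (n_C + 6A/26)$ — exactly 0.5 for a protein costing 26 ATP per 6
carbons, a stoichiometric identity the tests assert. Organism-level cost is
the expression-weighted mean over the (pre-flagged) secreted enzyme set.
Expression weights are predicted from codon usage bias: relative
adaptiveness $w$ from a user-designated highly expressed reference set
(ribosomal proteins are the natural default; zero reference counts floored
at 0.5), per-gene CAI as the geometric mean of $w$ over codons in
multi-codon families, weights proportional to CAI. CAI is one defensible
codon-bias expression proxy among several; the weighting input is a plain
per-gene quantity, so any alternative statistic can be substituted.
Identification of which proteins are extracellular is upstream of this
package; `flag_extracellular()` offers only the classic annotation keyword
stems as a convenience.

## Auxiliary statistics

* `rmcorr()`: the common within-subject correlation (ANCOVA with subject
  factor and common slope), $r = S_{xy}/\sqrt{S_{xx}S_{yy}}$ on
  subject-centred data, $N - k - 1$ df, t-based p. It is invariant to
  per-subject location shifts and reduces exactly to Pearson with one
  subject.
* `hartigan_dip()`: the dip statistic via the iterative greatest-convex-
  minorant / least-concave-majorant algorithm on the sorted sample, with a
  Monte-Carlo p value against the uniform null (the classical
  least-favourable calibration), 2000 null samples by default and a
  precomputable null table for batch testing. The statistic is affine- but
  not monotone-invariant (it depends on spacings, not ranks), respects the
  $1/(2n)$ lower bound on non-constant samples, and reaches its bimodal
  extreme of 0.25 on two balanced atoms. Applied to CUE, the natural unit
  is the per-isolate mean within an assay condition.

## The synthetic-data generator

The generator is the package's study design, not a tuning knob; its defaults
are fixed and the tests measure the pipeline against them.

* **Growth curves**: three phases — flat lag, exact exponential, logistic
  approach to carrying capacity (switching at half the maximum OD). The
  respired carbon is the exact integral of $R\,B(t)$, so noiseless curves
  recover CUE to numerical precision by construction. OD noise is
  multiplicative log-normal (read error grows with signal; sd 0.01 chosen
  for testability — real instrument error is not printed anywhere to copy);
  CO2 noise is additive in ppm. What is *not* emulated: substrate
  depletion/diauxie, CO2 dissolution kinetics, evaporation.
* **Trees and traits**: Yule/birth–death trees (`ape::rphylo`);
  λ-transformed Brownian traits drawn from the exact multivariate normal
  (empirical tip covariance converges to $\sigma^2 V_\lambda$, tested
  elementwise at 2000 draws within Monte-Carlo error).
* **Genomes**: KO latent log densities mix a Brownian tree component with
  independent noise; a per-KO prevalence target zero-truncates the smallest
  values, creating the rare-function tail the prevalence filter must
  remove. Counts are near-deterministic given the latent density
  (negative-binomial dispersion 0.05 — genome annotation counts are almost
  exact, and heavy count noise would be biologically wrong).
* **CUE over taxa**: baseline 0.55 plus planted effects plus noise with a
  small Brownian component (sd 0.02) and a larger independent component
  (sd 0.03), i.e. an underlying λ near 0.3. This mirrors the weak,
  inconsistent phylogenetic signal measured isolate CUE actually shows
  (K mostly well below 1, λ spanning 0 to 1 across conditions); a pure
  Brownian noise choice would both be unrealistic on that evidence and make
  every residual-signal check fail by construction.
* **Planted markers**: the causal KOs co-occur (latent pathway factor,
  correlation 0.85, all effects positive). This is a modelling necessity,
  not a convenience: with k independent causal features, the other k−1 act
  as residual variance in each feature's marginal test, which caps the
  achievable marginal power below any useful target at these sample sizes.
  The planted slope is set by the marginal-power formula documented in
  `simulate_marker_study()`, using two design constants measured once from
  pilot draws of the generator itself (realized density correlation 0.55;
  PGLS design effect 1.3) and a nominal exploration power target of ~0.9.
* **Communities**: simulated directly as (relative KO abundance, CUE)
  pairs with the same causal factor structure and small CUE noise
  (sd 0.01) — a strong, monotone link. Isotope-tracer mechanics,
  compositional coupling with the full metagenome, and 16S-inference error
  are *not* emulated; passing the community-validation tests shows the
  pipeline's logic is correct, not that real microcosm validation has this
  power.

## Problem sizes and reproducibility

The test suite and `scripts/acceptance.R` use these study sizes, chosen to
estimate each operating characteristic to useful Monte-Carlo precision: 200
growth replicates for CUE recovery; 1000 (tests) / 500 (script) conditions
for Q10 coverage with 1000 bootstrap resamples; 500/300 Brownian and null
simulations for K on a fixed 32-tip tree with 999 permutations; 200/100
replicates per λ level at 64 tips; 100 designs for the OLS identity and
200/150 for slope recovery; 50/30 null seeds and 30/20 power seeds for the
marker screen at 2000 KOs and 40 taxa; 50 five-tip trees for the re-rooting
oracle; 200/150 bimodal samples at n = 100 for dip power. All stochastic
stages take explicit seeds; `run_pipeline()` derives per-stage streams from
one master seed and records file hashes in a manifest, so a rerun with the
same configuration is bit-identical.
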