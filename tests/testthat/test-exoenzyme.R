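toy_table <- function(cost = 10) {
  tibble::tibble(
    residue = names(cuephylo:::AA_CARBONS),
    atp_cost = cost,
    n_carbon = unname(cuephylo:::AA_CARBONS)
  )
}

test_that("residue carbon counts follow standard chemistry", {
  tb <- toy_table()
  expect_equal(residue_carbons("G", tb), 2)
  expect_equal(residue_carbons("GG", tb), 4)
  expect_equal(residue_carbons("W", tb), 11)
  expect_equal(residue_carbons("GAVW", tb), 2 + 3 + 5 + 11)
  expect_error(residue_carbons("", tb), "empty")
  expect_error(residue_carbons("GXZ", tb), "unknown")
  expect_warning(got <- residue_carbons("GXG", tb, on_unknown = "skip"),
                 "skipping")
  expect_equal(got, 4)
})

test_that("protein ATP cost adds biosynthesis and bond formation", {
  tb <- toy_table(cost = 10)
  prm <- cost_parameters()
  expect_equal(protein_atp_cost("G", tb, prm), 10) # no bonds
  tb2 <- tb
  tb2$atp_cost[tb2$residue == "A"] <- 7
  expect_equal(protein_atp_cost("GA", tb2, prm), 10 + 7 + 4.2)
  L <- 12
  expect_equal(protein_atp_cost(strrep("V", L), tb, prm),
               L * 10 + 4.2 * (L - 1))
})

test_that("the 26-ATP-per-6-C stoichiometry forces the CUE identities", {
  prm <- cost_parameters(atp_per_bond = 4.2, atp_per_glucose = 26,
                         carbons_per_glucose = 6)
  # craft a tripeptide of glycines with total ATP exactly 26 and 6 carbons
  tb <- toy_table(cost = (26 - 2 * 4.2) / 3)
  expect_equal(protein_atp_cost("GGG", tb, prm), 26, tolerance = 1e-12)
  expect_equal(residue_carbons("GGG", tb), 6)
  expect_equal(protein_cue("GGG", tb, prm), 0.5, tolerance = 1e-12)
  # doubling the ATP at fixed carbon: 6 / (6 + 12) = 1/3
  tb52 <- toy_table(cost = (52 - 2 * 4.2) / 3)
  expect_equal(protein_cue("GGG", tb52, prm), 1 / 3, tolerance = 1e-12)
  # zero-cost world: nothing is respired
  prm0 <- cost_parameters(atp_per_bond = 1e-12)
  tb0 <- toy_table(cost = 0)
  expect_gt(protein_cue("GGG", tb0, prm0), 0.999999)
})

test_that("protein CUE is monotone in the stoichiometric constants", {
  tb <- toy_table(cost = 12)
  seqs <- "MAVGWKDE"
  bonds <- seq(2, 8, by = 0.5)
  cues_bond <- vapply(bonds, function(b) {
    protein_cue(seqs, tb, cost_parameters(atp_per_bond = b))
  }, numeric(1))
  expect_true(all(diff(cues_bond) < 0)) # costlier bonds, lower efficiency
  atps <- seq(20, 32, by = 1)
  cues_atp <- vapply(atps, function(a) {
    protein_cue(seqs, tb, cost_parameters(atp_per_glucose = a))
  }, numeric(1))
  expect_true(all(diff(cues_atp) > 0)) # more ATP per glucose, less C respired
})

test_that("protein CUE matches a glucose mass-balance oracle", {
  tb <- read_cost_table()
  prm <- cost_parameters()
  for (s in c("MKT", "GAVLWY", strrep("ADE", 20))) {
    atp <- protein_atp_cost(s, tb, prm)
    nc <- residue_carbons(s, tb)
    glucose_burned <- atp / prm$atp_per_glucose     # molecules fully oxidised
    c_respired <- glucose_burned * prm$carbons_per_glucose
    expect_equal(protein_cue(s, tb, prm), nc / (nc + c_respired),
                 tolerance = 1e-12)
  }
})

test_that("codon relative adaptiveness and CAI follow the reference usage", {
  # reference with known counts: Phe family TTT:3, TTC:1 -> w = 1, 1/3
  ref <- c(rep("TTT", 3), "TTC")
  ref_cds <- paste(ref, collapse = "")
  cb <- codon_bias_weights(c(g1 = "TTTTTT"), ref_cds)
  w <- setNames(cb$w$w, cb$w$codon)
  expect_equal(unname(w["TTT"]), 1)
  expect_equal(unname(w["TTC"]), 1 / 3)
  expect_equal(cb$cai$cai[1], 1) # only preferred codons used

  # two-codon toy gene with w = 0.5 and 0.125 -> CAI = 0.25
  # build a reference giving those ratios: GGA:8,GGC:4 (w=0.5), CTA:8,CTG:1 (w=0.125)
  ref2 <- paste(c(rep("GGA", 8), rep("GGC", 4), rep("CTA", 8), "CTG"),
                collapse = "")
  cb2 <- codon_bias_weights(c(g = "GGCCTG"), ref2)
  expect_equal(cb2$cai$cai[1], sqrt(0.5 * 0.125), tolerance = 1e-12)

  # uniform synonymous reference usage makes every w and CAI equal to 1
  ct <- cuephylo:::codon_table()
  uniform_ref <- paste(ct$codon, collapse = "")
  cb3 <- codon_bias_weights(c(a = "GGAGGCGGG"), uniform_ref)
  expect_equal(cb3$cai$cai[1], 1)

  expect_error(codon_bias_weights("TTTT", ref_cds), "divisible")
  expect_warning(codon_bias_weights(c(x = "TTTTAATTT"), ref_cds), "stop")
})

test_that("organism CUE is the expression-weighted mean of per-protein CUEs", {
  tb <- toy_table(cost = 10)
  prm <- cost_parameters()
  sim <- simulate_cds(4, codon_bias_strength = 0.7, seed = 3)
  res <- organism_exoenzyme_cue(sim$protein, sim$cds, tb, prm,
                                reference_cds = sim$cds)
  expect_equal(sum(res$per_protein$weight), 1)
  expect_equal(res$organism$cue_weighted,
               sum(res$per_protein$cue_protein * res$per_protein$weight))
  # convexity: organism value lies within the per-protein range
  expect_gte(res$organism$cue_weighted, min(res$per_protein$cue_protein))
  expect_lte(res$organism$cue_weighted, max(res$per_protein$cue_protein))
  # single protein: weight is irrelevant
  one <- organism_exoenzyme_cue(sim$protein[1], sim$cds[1], tb, prm,
                                reference_cds = sim$cds)
  expect_equal(one$organism$cue_weighted, one$per_protein$cue_protein[1])
  # order invariance
  perm <- c(3, 1, 4, 2)
  res2 <- organism_exoenzyme_cue(sim$protein[perm], sim$cds[perm], tb, prm,
                                 reference_cds = sim$cds)
  expect_equal(res2$organism$cue_weighted, res$organism$cue_weighted,
               tolerance = 1e-12)
  expect_error(
    organism_exoenzyme_cue(sim$protein[1:2], sim$cds[3:4], tb, prm),
    "ids do not match"
  )
})

test_that("uniform weights apply when no expression model is supplied", {
  tb <- toy_table(cost = 10)
  sim <- simulate_cds(3, seed = 9)
  res <- organism_exoenzyme_cue(sim$protein, sim$cds, tb)
  expect_equal(res$per_protein$weight, rep(1 / 3, 3))
  expect_equal(res$organism$cue_weighted, mean(res$per_protein$cue_protein))
})

test_that("keyword flagging matches secreted-enzyme annotation stems", {
  ann <- tibble::tibble(
    id = sprintf("p%d", 1:5),
    annotation = c("serine Protease", "alkaline phosphatase",
                   "aminopeptidase N", "DNA polymerase", "phospholipase C")
  )
  out <- flag_extracellular(ann)
  expect_equal(out$extracellular, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("the bundled cost table template is complete and valid", {
  tb <- read_cost_table()
  expect_setequal(tb$residue, names(cuephylo:::AA_CARBONS))
  expect_equal(setNames(tb$n_carbon, tb$residue)[names(cuephylo:::AA_CARBONS)],
               cuephylo:::AA_CARBONS, ignore_attr = TRUE)
  expect_true(all(tb$atp_cost > 0))
})
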