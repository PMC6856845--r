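test_that("generator configuration is validated", {
  expect_error(generator_config(p_ciat_given_motif = 1.2), "\\[0,1\\]")
  expect_error(generator_config(n_compounds = 0), "positive")
  expect_error(generator_config(
    n_primary_assays = 3,
    multiplicity_dist = c("1" = 0.5, "4" = 0.5)), "support")
  expect_error(generator_config(
    multiplicity_dist = c("2" = 1)), "mass to multiplicity 1")
  expect_warning(generator_config(
    multiplicity_dist = c("1" = 1)), "Set A will be empty")
  expect_error(generator_config(target_ciat_prevalence = 1.5), "\\(0,1\\)")
})

test_that("library generation is seed-deterministic and duplicate-free", {
  cfg <- generator_config(n_compounds = 400, seed = 7)
  lib1 <- generate_library(cfg)
  lib2 <- generate_library(cfg)
  expect_identical(lib1, lib2)
  expect_equal(nrow(lib1), 400)
  expect_false(anyDuplicated(canonical_smiles(lib1$smiles)) > 0)

  lib3 <- generate_library(generator_config(n_compounds = 400, seed = 8))
  expect_false(identical(lib1$smiles, lib3$smiles))
})

test_that("motif planting matches the configured fraction (independent matcher)", {
  cfg0 <- generator_config(n_compounds = 300, motif_fraction = 0, seed = 3)
  lib0 <- generate_library(cfg0)
  expect_true(all(is.na(lib0$motif_technology)))
  motifs <- default_interference_motifs()
  mols <- ChemmineOB::forEachMol(
    "SMILES", paste0(paste(lib0$smiles, lib0$compound_id, sep = "\t"),
                     collapse = "\n"), identity)
  for (i in seq_len(nrow(motifs))) {
    expect_equal(
      sum(ChemmineOB::smartsSearch_OB(mols, motifs$smarts[i],
                                      uniqueMatches = TRUE) > 0), 0,
      info = motifs$name[i])
  }

  # fraction 0.1 per technology over three technologies = 30 % carriers
  cfg <- generator_config(n_compounds = 1000, motif_fraction = 0.1, seed = 9)
  lib <- generate_library(cfg)
  expect_equal(sum(!is.na(lib$motif_technology)), 300)
  mols <- ChemmineOB::forEachMol(
    "SMILES", paste0(paste(lib$smiles, lib$compound_id, sep = "\t"),
                     collapse = "\n"), identity)
  any_motif <- rep(FALSE, nrow(lib))
  for (i in seq_len(nrow(motifs))) {
    any_motif <- any_motif |
      (ChemmineOB::smartsSearch_OB(mols, motifs$smarts[i],
                                   uniqueMatches = TRUE) > 0)
  }
  expect_equal(sum(any_motif), 300)
  expect_identical(unname(any_motif), !is.na(lib$motif_technology))
})

test_that("unsatisfiable motif fractions error, naming the stratum", {
  expect_error(
    generate_library(generator_config(n_compounds = 20000,
                                      motif_fraction = 0.3, seed = 1)),
    "unsatisfiable motif fraction")
})

test_that("ground truth follows the motif-conditional probabilities", {
  cfg <- generator_config(n_compounds = 1000, motif_fraction = 0.1, seed = 13,
                          p_ciat_given_motif = 1, p_ciat_no_motif = 0)
  lib <- generate_library(cfg)
  gt <- assign_ground_truth(lib, cfg)
  for (tech in cfg$technologies) {
    carrier <- !is.na(lib$motif_technology) & lib$motif_technology == tech
    expect_identical(gt[[tech]], carrier)
  }

  cfg2 <- generator_config(n_compounds = 2000, motif_fraction = 0.1, seed = 14,
                           p_ciat_given_motif = 0.9, p_ciat_no_motif = 0.05)
  lib2 <- generate_library(cfg2)
  gt2 <- assign_ground_truth(lib2, cfg2)
  for (tech in cfg2$technologies) {
    carrier <- !is.na(lib2$motif_technology) & lib2$motif_technology == tech
    r1 <- mean(gt2[[tech]][carrier])
    r0 <- mean(gt2[[tech]][!carrier])
    expect_lt(abs(r1 - 0.9), 3 * sqrt(0.9 * 0.1 / sum(carrier)))
    expect_lt(abs(r0 - 0.05), 3 * sqrt(0.05 * 0.95 / sum(!carrier)))
  }
})

test_that("campaigns are reproducible and structurally consistent", {
  cmp <- get_small_campaign()
  cmp2 <- simulate_campaign(small_campaign_config())
  expect_identical(cmp$results, cmp2$results)
  expect_identical(cmp$ground_truth, cmp2$ground_truth)

  # every linked primary assay has exactly one artefact partner
  linked <- cmp$assays[cmp$assays$assay_kind == "primary" &
                         !is.na(cmp$assays$linked_artefact), ]
  expect_true(all(linked$linked_artefact %in%
                    cmp$assays$assay_id[cmp$assays$assay_kind == "artefact"]))
  expect_false(anyDuplicated(linked$linked_artefact) > 0)

  # every compound active in a linked primary assay has an artefact result
  for (tech in cmp$config$technologies) {
    prim <- cmp$results[cmp$results$assay_id %in%
                          linked$assay_id[linked$technology == tech], ]
    act <- unique(prim$compound_id[prim$activity_flag == "active"])
    art <- cmp$results[cmp$results$technology == tech &
                         cmp$results$assay_kind == "artefact", ]
    expect_true(all(act %in% art$compound_id))
  }

  # ground truth defined for every compound
  expect_setequal(cmp$ground_truth$compound_id, cmp$compounds$compound_id)

  # realized prevalence near the configured target
  expect_true(all(abs(cmp$realized$ciat_prevalence_among_actives - 0.224)
                  <= 0.05))
})

test_that("multiplicity degenerate at 1 leaves no Set A compounds", {
  suppressWarnings(cfg <- generator_config(
    n_compounds = 600, n_primary_assays = 3, seed = 5,
    multiplicity_dist = c("1" = 1), target_ciat_prevalence = NA))
  cmp <- simulate_campaign(cfg)
  linked <- cmp$assays[cmp$assays$technology == "AlphaScreen" &
                         cmp$assays$assay_kind == "primary" &
                         !is.na(cmp$assays$linked_artefact), ]
  prim <- cmp$results[cmp$results$assay_id %in% linked$assay_id, ]
  membership <- unique(prim[, c("compound_id", "assay_id")])
  for (holdout in linked$assay_id) {
    ids <- unique(prim$compound_id[prim$assay_id == holdout &
                                     prim$activity_flag == "active"])
    sets <- split_sets(ids, holdout, membership)
    expect_length(sets$set_a, 0)
    expect_setequal(sets$set_b, ids)
  }
})

test_that("noiseless campaigns are exactly recoverable by curation", {
  cfg0 <- generator_config(
    n_compounds = 800, n_primary_assays = 3, seed = 5,
    multiplicity_dist = c("1" = 0.5, "2" = 0.3, "3" = 0.2),
    artefact_flip_noise = 0, p_ciat_given_motif = 1, p_ciat_no_motif = 0,
    inconclusive_rate = 0, target_ciat_prevalence = NA, base_hit_rate = 0.15)
  cmp0 <- simulate_campaign(cfg0)
  for (tech in cfg0$technologies) {
    ds <- curate_campaign(cmp0, technologies = tech)[[tech]]
    truth <- cmp0$ground_truth[[tech]][match(ds$table$compound_id,
                                             cmp0$ground_truth$compound_id)]
    expect_equal(mean((ds$table$label == "CIAT") == truth), 1)
  }
})
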