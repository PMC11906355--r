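test_that("variant-span checks respect coordinates and the flank margin", {
  expect_true(spans_variant(10, 25, 17))
  expect_true(spans_variant(10, 25, 26, flank = 1))   # cleavage-adjacent
  expect_true(spans_variant(10, 25, 9, flank = 1))
  expect_false(spans_variant(10, 25, 30))
  expect_false(spans_variant(10, 25, 27, flank = 1))
  expect_error(spans_variant(10, 25, NA_integer_), "aa_pos missing")
})

tier_fixture <- function(n_sig, n_total, consequence = "intergenic",
                         in_gene = FALSE, spanning = FALSE,
                         directions = rep(1, n_sig)) {
  structure(list(variant_id = "v", protein_id = "p",
                 n_peptides_total = n_total, n_peptides_significant = n_sig,
                 directions = directions, significant_peptides = character(n_sig),
                 consequence = consequence, in_gene = in_gene,
                 aa_pos = 10L, spanning = spanning,
                 tier = "unclassified", reason = NA_character_),
            class = "tier_record")
}

test_that("the tier decision tree follows the published rules exactly", {
  # >= 2 concordant supporting peptides
  expect_equal(assign_tier(tier_fixture(3, 5))$tier, "tier1")
  expect_equal(assign_tier(tier_fixture(2, 2, directions = c(1, 1)))$tier, "tier1")
  # discordant multi-peptide support is surfaced, not silently tiered
  disc <- assign_tier(tier_fixture(2, 2, directions = c(1, -1)))
  expect_equal(disc$tier, "unclassified")
  expect_match(disc$reason, "discordant")
  # single peptide, missense, outside the coding gene
  expect_equal(assign_tier(tier_fixture(1, 2, "missense", in_gene = FALSE))$tier, "tier2")
  # single peptide, missense inside the gene, peptide avoids the residue
  expect_equal(assign_tier(tier_fixture(1, 2, "missense", in_gene = TRUE,
                                        spanning = FALSE))$tier, "tier3")
  # ... but a spanning peptide is an artefact
  expect_equal(assign_tier(tier_fixture(1, 2, "missense", in_gene = TRUE,
                                        spanning = TRUE))$tier, "excluded_artefact")
  expect_equal(assign_tier(tier_fixture(1, 5, "missense", in_gene = TRUE,
                                        spanning = TRUE))$tier, "excluded_artefact")
  # single peptide, synonymous
  expect_equal(assign_tier(tier_fixture(1, 3, "synonymous"))$tier, "tier4")
  # single peptide of more than three testable -> unclassified
  u <- assign_tier(tier_fixture(1, 4, "synonymous"))
  expect_equal(u$tier, "unclassified")
  expect_match(u$reason, "more than three")
  # no significant peptides
  expect_equal(assign_tier(tier_fixture(0, 4))$tier, "unclassified")
})

test_that("tier assignment is total and deterministic over random records", {
  set.seed(41)
  labels <- c("tier1", "tier2", "tier3", "tier4", "excluded_artefact", "unclassified")
  for (i in 1:200) {
    ns <- sample(0:4, 1)
    rec <- tier_fixture(ns, ns + sample(0:3, 1),
                        sample(c("missense", "synonymous", "intergenic"), 1),
                        in_gene = runif(1) < 0.5, spanning = runif(1) < 0.5,
                        directions = sample(c(-1, 1), ns, replace = TRUE))
    out1 <- assign_tier(rec)
    out2 <- assign_tier(rec)
    expect_identical(out1$tier, out2$tier)
    expect_true(out1$tier %in% labels)
  }
})

test_that("peptide support separates genuine, artefactual and null pQTLs", {
  cfg <- sim_config(
    n_samples = 500L, n_variants = 30L, n_proteins = 6L,
    peptides_per_protein = c(5L, 5L), maf_range = c(0.2, 0.4),
    planted_effects = list(
      planted_effect(3L, 1L, 1.2, "cis"),
      planted_effect(7L, 2L, 0, "artefact", artefact_peptide = 2L, aa_pos = 60L)),
    seed = 42L)
  b <- simulate_cohort(cfg)
  pep <- prepare_phenotypes(b, "peptide")
  samp <- rownames(pep)

  # genuine: all five peptides respond concordantly
  v1 <- b$variants[3, ]
  rec1 <- assign_tier(peptide_support(pep, b$peptide_map, b$dosage[samp, 3],
                                      "PROT0001", v1, b$gene_map))
  expect_equal(rec1$n_peptides_total, 5L)
  expect_gte(rec1$n_peptides_significant, 2L)
  expect_equal(rec1$tier, "tier1")
  expect_equal(length(unique(rec1$directions)), 1L)

  # artefact: only the spanning peptide responds
  v2 <- b$variants[7, ]
  rec2 <- assign_tier(peptide_support(pep, b$peptide_map, b$dosage[samp, 7],
                                      "PROT0002", v2, b$gene_map))
  expect_equal(rec2$n_peptides_significant, 1L)
  expect_true(rec2$spanning)
  expect_equal(rec2$tier, "excluded_artefact")

  # null variant, null protein
  v3 <- b$variants[20, ]
  rec3 <- assign_tier(peptide_support(pep, b$peptide_map, b$dosage[samp, 20],
                                      "PROT0004", v3, b$gene_map))
  expect_equal(rec3$n_peptides_significant, 0L)
  expect_equal(rec3$tier, "unclassified")
})

test_that("concordance summary counts multi-peptide sign agreement", {
  tiers <- data.frame(n_peptides_significant = c(3, 2, 2, 1),
                      concordant = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(concordance_summary(tiers), 2 / 3)
  one <- data.frame(n_peptides_significant = 2, concordant = TRUE)
  expect_equal(concordance_summary(one), 1)
  expect_warning(val <- concordance_summary(one[0, ]), "no pQTLs")
  expect_true(is.na(val))
})
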