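test_that("configuration validation rejects impossible parameters", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_decay = 1.5), "ld_decay")
  expect_error(sim_config(noise_sd_protein = -1), "noise SDs")
  expect_error(sim_config(n_variants = 10, planted_effects =
                            list(planted_effect(11, 1, 0.5, "cis"))),
               "out of range")
  expect_error(planted_effect(1, 1, 0.5, "artefact"), "require")
  expect_error(planted_effect(1, 1, 0.5, "artefact", 1, 10), "beta = 0")
})

test_that("genotypes follow Hardy-Weinberg proportions and the requested MAF", {
  cfg <- sim_config(n_samples = 10000L, n_variants = 5L, n_proteins = 2L,
                    maf_range = c(0.3, 0.3), seed = 11L)
  g <- simulate_genotypes(cfg)
  af <- colMeans(g$dosage) / 2
  expect_true(all(abs(af - 0.3) < 0.01))  # binomial SE ~ 0.0032

  cfg5 <- sim_config(n_samples = 20000L, n_variants = 3L, n_proteins = 2L,
                     maf_range = c(0.5, 0.5), seed = 12L)
  g5 <- simulate_genotypes(cfg5)
  freqs <- table(factor(g5$dosage[, 1], levels = 0:2)) / 20000
  expect_equal(as.numeric(freqs), c(0.25, 0.5, 0.25), tolerance = 0.03)
})

test_that("the LD copy chain spans independence to perfect correlation", {
  cfg1 <- sim_config(n_samples = 2000L, n_variants = 5L, n_proteins = 2L,
                     ld_decay = 1, seed = 3L)
  g1 <- simulate_genotypes(cfg1)
  expect_equal(ld_r2(g1$dosage[, 1], g1$dosage[, 2]), 1)

  cfg0 <- sim_config(n_samples = 10000L, n_variants = 5L, n_proteins = 2L,
                     ld_decay = 0, seed = 4L)
  g0 <- simulate_genotypes(cfg0)
  expect_lt(ld_r2(g0$dosage[, 1], g0$dosage[, 2]), 0.01)
})

test_that("independent variants rarely fail the HWE test", {
  cfg <- sim_config(n_samples = 1000L, n_variants = 500L, n_proteins = 2L,
                    ld_decay = 0, seed = 5L)
  g <- simulate_genotypes(cfg)
  hwe_p <- apply(g$dosage, 2, function(d) {
    hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))$p
  })
  expect_gte(mean(hwe_p > 1e-6), 0.999)
})

test_that("noiseless cis effects shift protein levels by exactly beta per allele", {
  cfg <- sim_config(n_samples = 300L, n_variants = 10L, n_proteins = 3L,
                    planted_effects = list(planted_effect(1L, 1L, 1.0, "cis")),
                    covariate_model = list(age = 0, sex = 0, bmi_sds = 0,
                                           obesity = 0, storage = 0),
                    noise_sd_protein = 0, noise_sd_peptide = 0,
                    missingness = list(intercept = -50, slope = 0), seed = 6L)
  b <- simulate_cohort(cfg)
  g <- b$dosage[, 1]
  skip_if(!any(g == 2) || !any(g == 0))
  d20 <- mean(b$protein[g == 2, 1]) - mean(b$protein[g == 0, 1])
  expect_equal(d20, 2, tolerance = 1e-12)
})

test_that("artefact peptides vanish in homozygous-alternate carriers only", {
  cfg <- sim_config(n_samples = 500L, n_variants = 10L, n_proteins = 3L,
                    peptides_per_protein = c(3L, 3L),
                    maf_range = c(0.4, 0.5),
                    planted_effects = list(
                      planted_effect(2L, 1L, 0, "artefact",
                                     artefact_peptide = 2L, aa_pos = 60L)),
                    missingness = list(intercept = -50, slope = 0), seed = 8L)
  b <- simulate_cohort(cfg)
  g <- b$dosage[, 2]
  art <- "PROT0001_pep02"
  sib <- "PROT0001_pep01"
  expect_true(all(is.na(b$peptide[g == 2, art])))
  expect_true(all(!is.na(b$peptide[g == 2, sib])))
  # heterozygotes keep the peptide at half linear intensity (-1 on log2)
  expect_equal(mean(b$peptide[g == 1, art]) - mean(b$peptide[g == 0, art]),
               -1, tolerance = 0.2)
  # the substitution position is recorded inside the artefact peptide span
  pm <- b$peptide_map[b$peptide_map$peptide_id == art, ]
  expect_true(spans_variant(pm$aa_start, pm$aa_end, 60L))
})

test_that("planted effect recovery is unbiased under OLS", {
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(n_samples = 1000L, n_variants = 5L, n_proteins = 2L,
                      maf_range = c(0.3, 0.3),
                      planted_effects = list(planted_effect(1L, 1L, 0.5, "cis")),
                      missingness = list(intercept = -50, slope = 0),
                      seed = 100L + s)
    cov <- simulate_covariates(cfg)
    g <- simulate_genotypes(cfg)
    pr <- simulate_proteome(cfg, g, cov)
    fit <- slr_oracle(g$dosage[, 1], pr$protein_complete[, 1])
    abs(fit$beta - 0.5) < 3 * fit$se
  }, logical(1))
  expect_gte(mean(hits), 0.94)
})

test_that("missingness is enriched at low intensities (MNAR contract)", {
  set.seed(9)
  mat <- matrix(rnorm(20000, 20, 3), 100, 200)
  obs <- apply_mnar(mat, list(intercept = 7.5, slope = -0.5))
  lost <- is.na(obs)
  expect_lt(mean(mat[lost]), mean(mat[!lost]))  # dropped cells are dimmer
  # missingness decreases monotonically across intensity terciles
  terc <- cut(mat, quantile(mat, c(0, 1/3, 2/3, 1)), include.lowest = TRUE)
  rates <- tapply(as.vector(lost), terc, mean)
  expect_gt(rates[1], rates[2])
  expect_gt(rates[2], rates[3])
})

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- sim_config(n_samples = 100L, n_variants = 20L, n_proteins = 5L, seed = 77L)
  b1 <- simulate_cohort(cfg)
  b2 <- simulate_cohort(cfg)
  expect_identical(b1$dosage, b2$dosage)
  expect_identical(b1$protein, b2$protein)
  expect_identical(b1$peptide, b2$peptide)
  expect_identical(b1$covariates, b2$covariates)
})

test_that("outcome GWAS reflects the causal chain through the protein", {
  cfg <- sim_config(n_samples = 1500L, n_variants = 10L, n_proteins = 2L,
                    maf_range = c(0.3, 0.5),
                    planted_effects = list(planted_effect(1L, 1L, 1.0, "cis")),
                    seed = 21L)
  # theta = 0: outcome effect at the cis variant centered on zero
  null_stats <- simulate_outcome_gwas(cfg, theta = 0, protein_index = 1L)
  expect_lt(abs(null_stats$beta[1]) / null_stats$se[1], 4)

  # noiseless trait = protein: outcome betas equal exposure betas exactly
  ident <- simulate_outcome_gwas(cfg, theta = 1, protein_index = 1L, noise_sd = 0)
  cfg2 <- cfg; cfg2$seed <- substream_seed(cfg$seed, "outcome-cohort")
  g2 <- simulate_genotypes(cfg2)
  pr2 <- simulate_proteome(cfg2, g2, simulate_covariates(cfg2))
  expo <- assoc_scan(g2$dosage, pr2$protein_complete[, 1])
  expect_equal(ident$beta, expo$beta, tolerance = 1e-12)

  # theta = 0.4 with a strong instrument: Wald ratio near 0.4
  out04 <- simulate_outcome_gwas(cfg, theta = 0.4, protein_index = 1L, noise_sd = 0.5)
  wr <- wald_ratio(expo$beta[1], expo$se[1], out04$beta[1], out04$se[1])
  expect_lt(abs(wr$wald_beta - 0.4), 3 * wr$wald_se)
})
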