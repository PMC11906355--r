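make_replication_pair <- function(seed, n = 500L) {
  # eight cis effects with a spread of sizes so the discovery/replication
  # beta correlation reflects true effect heterogeneity, not noise
  betas <- seq(0.5, 2.5, length.out = 8)
  effects <- lapply(1:8, function(i) planted_effect(i * 10L - 5L, i, betas[i], "cis"))
  cfg_d <- sim_config(n_samples = n, n_variants = 80L, n_proteins = 10L,
                      planted_effects = effects, seed = seed)
  disc <- simulate_cohort(cfg_d)
  # the replication cohort is an independent draw from the same population:
  # same allele frequencies, fresh samples
  cfg_r <- sim_config(n_samples = n, n_variants = 80L, n_proteins = 10L,
                      maf_fixed = disc$variants$maf,
                      planted_effects = effects, seed = seed + 5000L)
  list(disc = disc, repl = simulate_cohort(cfg_r))
}

test_that("strong planted pQTLs replicate in an independent cohort", {
  pair <- make_replication_pair(81L)
  ph_d <- prepare_phenotypes(pair$disc, "protein")
  pq <- map_pqtls(pair$disc$dosage[rownames(ph_d), ], pair$disc$variants,
                  ph_d, pair$disc$gene_map)
  expect_gte(nrow(pq), 3)
  ph_r <- prepare_phenotypes(pair$repl, "protein")
  rr <- replicate_pqtls(pq, pair$repl$dosage[rownames(ph_r), ], ph_r)
  expect_gte(rr$summary$rate_overall, 0.95)
  expect_gte(rr$summary$beta_r, 0.9)
  expect_true(all(rr$records$eligible[rr$records$replicated]))
})

test_that("replicating a cohort against itself is perfect", {
  pair <- make_replication_pair(82L, n = 400L)
  ph <- prepare_phenotypes(pair$disc, "protein")
  dos <- pair$disc$dosage[rownames(ph), ]
  pq <- map_pqtls(dos, pair$disc$variants, ph, pair$disc$gene_map)
  rr <- replicate_pqtls(pq, dos, ph)
  expect_equal(rr$summary$rate_overall, 1)
  expect_equal(rr$summary$beta_r, 1, tolerance = 1e-12)
  expect_equal(rr$records$rep_beta, rr$records$beta_lead, tolerance = 1e-12)
})

test_that("null replication cohorts replicate at roughly the chance rate", {
  # discovery records pointed at a cohort with no planted effects: the
  # sign-concordant nominal rate is at most alpha and close to alpha/2
  cfg_null <- sim_config(n_samples = 500L, n_variants = 100L, n_proteins = 5L,
                         seed = 83L)
  b <- simulate_cohort(cfg_null)
  ph <- prepare_phenotypes(b, "protein")
  set.seed(84)
  fake <- data.frame(protein_id = sample(colnames(ph), 400, replace = TRUE),
                     variant_id = sample(colnames(b$dosage), 400, replace = TRUE),
                     beta_lead = rnorm(400), se_lead = 0.1, p_lead = 1e-10,
                     cis = TRUE, stringsAsFactors = FALSE)
  rr <- replicate_pqtls(fake, b$dosage[rownames(ph), ], ph)
  expect_lt(rr$summary$rate_overall, 0.07)
  expect_gt(rr$summary$rate_overall, 0.001)
})

test_that("replication summaries ignore record order", {
  pair <- make_replication_pair(85L, n = 300L)
  ph_d <- prepare_phenotypes(pair$disc, "protein")
  pq <- map_pqtls(pair$disc$dosage[rownames(ph_d), ], pair$disc$variants,
                  ph_d, pair$disc$gene_map)
  ph_r <- prepare_phenotypes(pair$repl, "protein")
  dos_r <- pair$repl$dosage[rownames(ph_r), ]
  r1 <- replicate_pqtls(pq, dos_r, ph_r)
  r2 <- replicate_pqtls(pq[rev(seq_len(nrow(pq))), ], dos_r, ph_r)
  expect_equal(r1$summary$rate_overall, r2$summary$rate_overall)
  expect_equal(r1$summary$beta_r, r2$summary$beta_r, tolerance = 1e-12)
})

test_that("novelty is a protein-matched 1 Mb window lookup", {
  pq <- data.frame(protein_id = c("P1", "P1", "P2"), chrom = c("1", "1", "2"),
                   pos = c(5e6, 9e6, 1e6), stringsAsFactors = FALSE)
  # empty published list: everything novel
  empty <- data.frame(protein_id = character(), chrom = character(),
                      pos = integer(), stringsAsFactors = FALSE)
  expect_true(all(assess_novelty(pq, empty)$novel))
  pub <- data.frame(protein_id = c("P1", "P2", "P9"), chrom = c("1", "2", "3"),
                    pos = c(5e6, 2.5e6, 1e6), stringsAsFactors = FALSE)
  out <- assess_novelty(pq, pub)
  expect_false(out$novel[1])  # exact position match
  expect_true(out$novel[2])   # same protein, 4 Mb away
  expect_true(out$novel[3])   # published entry 1.5 Mb away
  expect_equal(attr(out, "unmatched_published"), 1)  # P9 matches nothing
})

test_that("the full pipeline is deterministic for a fixed seed", {
  cfg <- sim_config(n_samples = 250L, n_variants = 60L, n_proteins = 8L,
                    planted_effects = list(planted_effect(10L, 1L, 1.2, "cis")),
                    seed = 86L)
  r1 <- run_pipeline(simulate_cohort(cfg))
  r2 <- run_pipeline(simulate_cohort(cfg))
  expect_identical(r1$pqtls, r2$pqtls)
  expect_identical(r1$pheno, r2$pheno)
  expect_identical(r1$prediction$age$test_mae, r2$prediction$age$test_mae)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
})
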