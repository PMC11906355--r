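test_that("LD r-squared is a squared Pearson correlation of dosages", {
  set.seed(31)
  g <- rbinom(10000, 2, 0.3)
  expect_equal(ld_r2(g, g), 1)
  h <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(g, h), 0.01)
  expect_error(ld_r2(g, rep(1, 10000)), "constant")
})


test_that("greedy clumping equals the brute-force oracle", {
  for (s in 1:200) {
    inst <- random_clump_instance(1000 + s)
    m <- nrow(inst$assoc)
    if (m < 2) next
    r2 <- cor(inst$dosage)^2
    got <- clump(inst$assoc, inst$variants, inst$dosage,
                 r2_min = 0.2, window_bp = 1e6, p_max = 0.3)
    oracle <- clump_oracle(inst$assoc$p, inst$variants$pos, inst$variants$chrom,
                           r2, p_max = 0.3, r2_min = 0.2, window = 1e6)
    expect_identical(got$variant_id, inst$assoc$variant_id[oracle$leads])
    got_members <- lapply(strsplit(got$members, ";"), sort)
    oracle_members <- lapply(oracle$members,
                             function(ix) sort(inst$assoc$variant_id[ix]))
    expect_identical(got_members, oracle_members)
  }
})

test_that("clumping honours the window and significance rules", {
  n <- 100
  set.seed(32)
  g <- matrix(rbinom(n * 2, 2, 0.3), n, 2, dimnames = list(NULL, c("a", "b")))
  g[, 2] <- g[, 1]  # perfect LD but 2 Mb apart
  variants <- data.frame(variant_id = c("a", "b"), chrom = "1",
                         pos = c(1e6, 3e6), stringsAsFactors = FALSE)
  assoc <- data.frame(variant_id = c("a", "b"), beta = c(1, 1),
                      se = c(0.1, 0.1), p = c(1e-10, 1e-9), stringsAsFactors = FALSE)
  out <- clump(assoc, variants, g)
  expect_equal(nrow(out), 2)  # window rule separates them

  # only one significant variant -> single clump of size one
  assoc$p <- c(1e-10, 0.5)
  out1 <- clump(assoc, variants, g)
  expect_equal(out1$variant_id, "a")
  expect_equal(out1$n_members, 1L)
  expect_error(clump(assoc, variants, g[, 1, drop = FALSE]), "genotypes missing")
})

test_that("cis/trans classification uses an inclusive 1 Mb TSS window", {
  gene_map <- data.frame(protein_id = "P1", gene_id = "G1", chrom = "1",
                         tss = 5e6, strand = "+", stringsAsFactors = FALSE)
  mk <- function(pos, chrom = "1") data.frame(protein_id = "P1", chrom = chrom,
                                              pos = pos, stringsAsFactors = FALSE)
  expect_true(classify_cis_trans(mk(5e6), gene_map)$cis)          # at TSS
  expect_equal(classify_cis_trans(mk(5e6), gene_map)$tss_distance, 0)
  expect_true(classify_cis_trans(mk(5e6 + 1e6), gene_map)$cis)    # boundary inclusive
  expect_false(classify_cis_trans(mk(5e6 + 1e6 + 1), gene_map)$cis)
  expect_false(classify_cis_trans(mk(5e6, chrom = "2"), gene_map)$cis)
  # upstream on the minus strand flips the sign of the distance
  gm_minus <- transform(gene_map, strand = "-")
  expect_equal(classify_cis_trans(mk(5e6 - 1000), gm_minus)$tss_distance, 1000)
  # unmapped protein -> NA label
  gm_other <- transform(gene_map, protein_id = "P2")
  expect_true(is.na(classify_cis_trans(mk(5e6), gm_other)$cis))
})

test_that("conditional analysis recovers the planted number of signals", {
  set.seed(33)
  n <- 1000
  g <- matrix(rbinom(n * 6, 2, 0.3), n, 6, dimnames = list(NULL, sprintf("v%d", 1:6)))
  # one signal
  y1 <- 0.5 * g[, 2] + rnorm(n)
  c1 <- conditional_scan(g, y1)
  expect_equal(nrow(c1), 1)
  expect_equal(c1$variant_id, "v2")
  # two independent signals
  recovered <- vapply(1:10, function(s) {
    set.seed(300 + s)
    gg <- matrix(rbinom(n * 6, 2, 0.3), n, 6, dimnames = list(NULL, sprintf("v%d", 1:6)))
    y2 <- 0.4 * gg[, 1] + 0.4 * gg[, 5] + rnorm(n)
    cs <- conditional_scan(gg, y2)
    nrow(cs) == 2 && setequal(cs$variant_id, c("v1", "v5"))
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
  # perfectly correlated pair collapses to one signal
  g2 <- cbind(a = g[, 1], b = g[, 1])
  y3 <- 0.5 * g[, 1] + rnorm(n)
  c3 <- conditional_scan(g2, y3)
  expect_equal(nrow(c3), 1)
})

test_that("study-wide thresholds reproduce the Bonferroni arithmetic", {
  expect_equal(signif(study_wide_threshold(5e-8, 1216), 2), 4.1e-11)
  expect_equal(study_wide_threshold(5e-8, 1), 5e-8)
  expect_equal(study_wide_threshold(0.05, 20000), 2.5e-6)
})

test_that("a strong planted cis effect maps to one cis-labelled primary pQTL", {
  b <- make_cis_bundle(seed = 34L, n = 600L, beta = 1.2)
  ph <- prepare_phenotypes(b, "protein")
  qc <- qc_genotypes(b$dosage[rownames(ph), ], b$variants)
  pq <- map_pqtls(qc$dosage, qc$variants, ph[rownames(qc$dosage), ], b$gene_map)
  hit <- pq[pq$protein_id == "PROT0001", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$variant_id, "var00010")
  expect_true(hit$cis)
})
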