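make_varexp_fixture <- function(n, seed, f_pqtl = 0.20, f_age = 0.10, f_sex = 0.05) {
  set.seed(seed)
  g <- rbinom(n, 2, 0.3)
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 5, 20),
                    obesity = rbinom(n, 1, 0.5), bmi_sds = rnorm(n))
  std <- function(x) (x - mean(x)) / sd(x)
  y <- sqrt(f_pqtl) * std(g) + sqrt(f_age) * std(cov$age) +
    sqrt(f_sex) * std(cov$sex) +
    sqrt(1 - f_pqtl - f_age - f_sex) * rnorm(n)
  list(y = y, g = matrix(g, ncol = 1), cov = cov)
}

test_that("planted variance fractions are recovered", {
  fx <- make_varexp_fixture(2000, seed = 51)
  dec <- decompose_variance(fx$y, fx$g, fx$cov)
  expect_lt(abs(dec$fractions["pqtl"] - 0.20), 0.03)
  expect_lt(abs(dec$fractions["age"] - 0.10), 0.03)
  expect_lt(abs(dec$fractions["sex"] - 0.05), 0.03)
  expect_lt(dec$fractions["obesity"], 0.01)
})

test_that("sequential fractions always total the full-model R-squared", {
  for (s in 1:10) {
    fx <- make_varexp_fixture(300, seed = 500 + s,
                              f_pqtl = runif(1, 0, 0.4), f_age = runif(1, 0, 0.2),
                              f_sex = runif(1, 0, 0.1))
    dec <- decompose_variance(fx$y, fx$g, fx$cov)
    expect_equal(sum(dec$fractions), dec$total_r2, tolerance = 1e-10)
    expect_true(all(dec$fractions >= 0))
    expect_lte(dec$total_r2, 1 + 1e-12)
  }
})

test_that("pure-noise proteins attribute almost nothing to any component", {
  fx <- make_varexp_fixture(2000, seed = 52, f_pqtl = 0, f_age = 0, f_sex = 0)
  dec <- decompose_variance(fx$y, fx$g, fx$cov)
  expect_true(all(dec$fractions < 0.01))
})

test_that("the decomposition is invariant to sample reordering", {
  fx <- make_varexp_fixture(400, seed = 53)
  dec1 <- decompose_variance(fx$y, fx$g, fx$cov)
  set.seed(54)
  perm <- sample(length(fx$y))
  dec2 <- decompose_variance(fx$y[perm], fx$g[perm, , drop = FALSE],
                             fx$cov[perm, ])
  expect_equal(dec1$fractions, dec2$fractions, tolerance = 1e-10)
  expect_error(decompose_variance(rep(1, 10), NULL, fx$cov[1:10, ]),
               "zero-variance")
})

test_that("age-stratified genetic fractions are stable when genetics is age-independent", {
  set.seed(55)
  n <- 3000
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 5, 20),
                    obesity = rbinom(n, 1, 0.5), bmi_sds = rnorm(n))
  n_prot <- 12
  g_list <- list(); ph <- matrix(NA_real_, n, n_prot,
                                 dimnames = list(NULL, sprintf("P%02d", 1:n_prot)))
  for (k in 1:n_prot) {
    g <- rbinom(n, 2, 0.3)
    frac <- 0.05 + 0.5 * (k - 1) / (n_prot - 1)  # spread of genetic contributions
    ph[, k] <- sqrt(frac) * (g - mean(g)) / sd(g) + sqrt(1 - frac) * rnorm(n)
    g_list[[sprintf("P%02d", k)]] <- matrix(g, ncol = 1)
  }
  st <- age_group_stability(ph, g_list, cov)
  expect_true(all(st$correlations$r > 0.9))
  # identical groups give r exactly 1
  st_same <- age_group_stability(ph, g_list, cov,
                                 breaks = list(c(5, 20), c(5, 20)))
  expect_equal(st_same$correlations$r, 1, tolerance = 1e-12)
  expect_error(age_group_stability(ph, g_list, cov,
                                   breaks = list(c(5, 9), c(30, 40))),
               "below minimum size")
})

test_that("a planted genotype-by-age interaction degrades cross-age stability", {
  set.seed(56)
  n <- 3000
  cov <- data.frame(sex = rbinom(n, 1, 0.5), age = runif(n, 5, 20),
                    obesity = rbinom(n, 1, 0.5), bmi_sds = rnorm(n))
  n_prot <- 12
  mk <- function(interact) {
    ph <- matrix(NA_real_, n, n_prot, dimnames = list(NULL, sprintf("P%02d", 1:n_prot)))
    g_list <- list()
    for (k in 1:n_prot) {
      g <- rbinom(n, 2, 0.3)
      base <- 0.05 + 0.5 * (k - 1) / (n_prot - 1)
      eff <- if (interact) sqrt(base) * (cov$age - 5) / 15 else sqrt(base)
      ph[, k] <- eff * (g - mean(g)) / sd(g) + rnorm(n)
      g_list[[sprintf("P%02d", k)]] <- matrix(g, ncol = 1)
    }
    min(age_group_stability(ph, g_list, cov)$correlations$r)
  }
  expect_lt(mk(TRUE), mk(FALSE))
})

test_that("allelic fold change reproduces the defining arithmetic", {
  ab <- c(rep(100, 4), rep(200, 4), rep(400, 4))
  ds <- rep(0:2, each = 4)
  afc <- allelic_fold_change(ab, ds)
  expect_equal(afc$afc_het, 2)
  expect_equal(afc$afc_hom, 4)
  expect_equal(afc$log2_fc_hom, 2)
  # identical group means
  same <- allelic_fold_change(rep(50, 9), rep(0:2, each = 3))
  expect_equal(same$afc_het, 1)
  expect_equal(same$log2_fc_hom, 0)
  # empty genotype group flagged, not fabricated
  noalt <- allelic_fold_change(c(10, 20), c(0, 1))
  expect_true(is.na(noalt$afc_hom))
  expect_equal(noalt$missing_groups, "hom_alt")
  expect_error(allelic_fold_change(c(-1, 2, 3), c(0, 1, 2)), "non-negative")
})

test_that("a noiseless multiplicative effect gives exact fold changes", {
  cfg <- sim_config(n_samples = 200L, n_variants = 5L, n_proteins = 2L,
                    maf_range = c(0.4, 0.5),
                    planted_effects = list(planted_effect(1L, 1L, 1.0, "cis")),
                    covariate_model = list(age = 0, sex = 0, bmi_sds = 0,
                                           obesity = 0, storage = 0),
                    noise_sd_protein = 0, noise_sd_peptide = 0,
                    missingness = list(intercept = -50, slope = 0), seed = 57L)
  b <- simulate_cohort(cfg)
  afc <- allelic_fold_change(2^b$protein[, 1], b$dosage[, 1])
  expect_equal(afc$afc_hom, 4, tolerance = 1e-12)
  expect_equal(afc$afc_het, 2, tolerance = 1e-12)
  # constructed directly on the linear scale the ratio is exact
  g <- b$dosage[, 1]
  expect_identical(allelic_fold_change(100 * 2^g, g)$afc_hom, 4)
})
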