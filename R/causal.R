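#' Harmonize exposure and outcome summary statistics at shared variants
#'
#' Matches variants by identifier, aligns effect alleles (flipping the
#' outcome beta when the effect/other alleles are swapped), rejects variants
#' whose allele pairs cannot be reconciled, and drops palindromic (A/T, C/G)
#' variants whose strand cannot be resolved.
#'
#' @param exposure,outcome summary-statistics data.frames (variant_id,
#'   effect_allele, other_allele, beta, se, pval, ...).
#' @return list with harmonized `exposure` and `outcome` tables (same row
#'   order) and counts of dropped variants.
#' @export
harmonize_stats <- function(exposure, outcome) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]
  pal <- toupper(paste0(ex$effect_allele, ex$other_allele)) %in% c("AT", "TA", "CG", "GC")
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  flipped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  bad <- !(same | flipped)
  if (any(pal)) log_msg("harmonize_stats: dropping ", sum(pal), " palindromic variants")
  keep <- !pal & !bad
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  fl <- flipped[keep]
  ou$beta[fl] <- -ou$beta[fl]
  tmp <- ou$effect_allele[fl]
  ou$effect_allele[fl] <- ou$other_allele[fl]
  ou$other_allele[fl] <- tmp
  list(exposure = ex, outcome = ou,
       n_dropped_palindromic = sum(pal), n_dropped_mismatch = sum(bad & !pal))
}

#' Wald-ratio Mendelian randomization at a single instrument
#'
#' Estimates the causal effect of the protein on the trait as the ratio of
#' outcome to exposure effect at one cis-pQTL, with first-order delta-method
#' standard error se_outcome / |beta_exposure| and a two-sided normal test.
#'
#' @param beta_exp,se_exp exposure (protein) effect and SE at the variant.
#' @param beta_out,se_out outcome (trait) effect and SE at the same variant,
#'   aligned to the same effect allele (see [harmonize_stats()]).
#' @param alpha_mr significance threshold (default 2.5e-6, a Bonferroni
#'   correction of 0.05 for roughly 20,000 protein-coding genes).
#' @param min_beta_exp weak-instrument guard: error when |beta_exp| falls
#'   below this tolerance.
#' @return list with wald_beta, wald_se, wald_p, significant.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       alpha_mr = 2.5e-6, min_beta_exp = 1e-8) {
  if (!is.finite(beta_exp) || abs(beta_exp) < min_beta_exp) {
    stop("exposure effect too small: weak or absent instrument")
  }
  wald_beta <- beta_out / beta_exp
  wald_se <- se_out / abs(beta_exp)
  z <- wald_beta / wald_se
  wald_p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(wald_beta = wald_beta, wald_se = wald_se, wald_p = wald_p,
       significant = wald_p < alpha_mr)
}

# Wakefield log approximate Bayes factor for one variant (H1 vs H0)
wakefield_labf <- function(beta, se, prior_sd) {
  v <- se^2
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * (log(v / (v + w)) + z2 * w / (v + w))
}

#' Two-trait colocalization by approximate Bayes factors
#'
#' Single-causal-variant Bayesian colocalization over a region shared by two
#' traits. Per-variant approximate Bayes factors are computed from (beta, se)
#' with a Normal(0, prior_sd^2) effect prior, and combined into posterior
#' probabilities of the five hypotheses: H0 no association; H1/H2 a causal
#' variant for one trait only; H3 two distinct causal variants; H4 one
#' shared causal variant.
#'
#' @param stats_a,stats_b summary-statistics data.frames with variant_id,
#'   beta, se for the same region; only shared variants are used.
#' @param p1,p2 prior probability that a variant is causal for trait A / B
#'   (default 1e-4).
#' @param p12 prior probability that a variant is causal for both (default
#'   1e-5).
#' @param prior_sd SD of the causal effect prior (default 0.15, the standard
#'   choice for quantitative traits).
#' @return named numeric PP0..PP4 summing to 1.
#' @export
coloc_abf <- function(stats_a, stats_b, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd = 0.15) {
  shared <- intersect(stats_a$variant_id, stats_b$variant_id)
  if (length(shared) < 2L) stop("need at least 2 overlapping variants for colocalization")
  a <- stats_a[match(shared, stats_a$variant_id), ]
  b <- stats_b[match(shared, stats_b$variant_id), ]
  l1 <- wakefield_labf(a$beta, a$se, prior_sd)
  l2 <- wakefield_labf(b$beta, b$se, prior_sd)
  lsum1 <- logsumexp(l1)
  lsum2 <- logsumexp(l2)
  lsum12 <- logsumexp(l1 + l2)
  # sum over ordered pairs i != j of BF1_i * BF2_j
  lh3_sum <- log_diff_exp(lsum1 + lsum2, lsum12)
  lh <- c(h0 = 0,
          h1 = log(p1) + lsum1,
          h2 = log(p2) + lsum2,
          h3 = log(p1) + log(p2) + lh3_sum,
          h4 = log(p12) + lsum12)
  post <- exp(lh - logsumexp(lh))
  stats::setNames(post / sum(post), c("PP0", "PP1", "PP2", "PP3", "PP4"))
}

# log(exp(a) - exp(b)) for a >= b, guarded against cancellation
log_diff_exp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Joint MR and colocalization for one (protein, trait) pair
#'
#' Runs the Wald-ratio test at the top cis instrument and approximate-Bayes-
#' factor colocalization over the surrounding region, and applies the
#' decision rule: causal support requires MR significance, PP4 at or above
#' `pp4_min` and a regional association probability (1 - PP0 - PP3) at or
#' above `regional_min`.
#'
#' @param exposure,outcome harmonizable regional summary statistics.
#' @param instrument variant_id of the top cis-pQTL instrument.
#' @param alpha_mr MR threshold (default 2.5e-6).
#' @param pp4_min colocalization posterior threshold (default 0.7).
#' @param regional_min regional probability threshold (default 0.6).
#' @param ... passed to [coloc_abf()].
#' @return list combining the MR fields, posteriors, and `colocalized` flag.
#' @export
causal_test <- function(exposure, outcome, instrument, alpha_mr = 2.5e-6,
                        pp4_min = 0.7, regional_min = 0.6, ...) {
  h <- harmonize_stats(exposure, outcome)
  i <- match(instrument, h$exposure$variant_id)
  if (is.na(i)) stop("instrument ", instrument, " absent after harmonization")
  mr <- wald_ratio(h$exposure$beta[i], h$exposure$se[i],
                   h$outcome$beta[i], h$outcome$se[i], alpha_mr = alpha_mr)
  pp <- coloc_abf(h$exposure, h$outcome, ...)
  regional <- 1 - pp["PP0"] - pp["PP3"]
  c(mr, list(posteriors = pp,
             regional_probability = unname(regional),
             colocalized = unname(pp["PP4"] >= pp4_min & regional >= regional_min)))
}
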