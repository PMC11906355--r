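# Independent reference implementations used to cross-check the package.
# These are deliberately naive (loops, textbook formulas) and never share
# code with the implementation under test.

# Closed-form simple linear regression of y on x with intercept.
slr_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  p <- 2 * pt(abs(b / se), df = n - 2, lower.tail = FALSE)
  list(beta = b, se = se, p = p)
}

# Step-up false-discovery-rate adjustment from the definition:
# q_i = min over j >= rank(i) of m * p_(j) / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (k in m:1) {
    running <- min(running, m * p[ord[k]] / k)
    q[ord[k]] <- min(running, 1)
  }
  q
}

# Greedy clump assignment by direct restatement of the rule: repeatedly pick
# the unassigned variant with smallest p (ties: smaller position) below
# p_max, then sweep all unassigned variants for r2 > r2_min and distance
# <= window.
clump_oracle <- function(p, pos, chrom, r2, p_max, r2_min, window) {
  m <- length(p)
  assigned <- rep(FALSE, m)
  leads <- integer(0)
  members <- list()
  repeat {
    cand <- which(!assigned & p < p_max)
    if (length(cand) == 0) break
    lead <- cand[order(p[cand], pos[cand])][1]
    assigned[lead] <- TRUE
    mem <- integer(0)
    for (j in seq_len(m)) {
      if (assigned[j]) next
      if (chrom[j] == chrom[lead] && abs(pos[j] - pos[lead]) <= window &&
          r2[j, lead] > r2_min) {
        assigned[j] <- TRUE
        mem <- c(mem, j)
      }
    }
    leads <- c(leads, lead)
    members[[length(members) + 1]] <- sort(c(lead, mem))
  }
  list(leads = leads, members = members)
}

# Wald ratio from first principles.
wald_oracle <- function(beta_exp, beta_out, se_out) {
  b <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  list(beta = b, se = se, p = 2 * pnorm(abs(b / se), lower.tail = FALSE))
}

# A tiny deterministic cohort with one strong planted cis effect, used by
# several module tests.
make_cis_bundle <- function(seed = 7L, n = 400L, beta = 1.0) {
  cfg <- sim_config(n_samples = n, n_variants = 50L, n_proteins = 10L,
                    peptides_per_protein = c(4L, 5L),
                    planted_effects = list(planted_effect(10L, 1L, beta, "cis")),
                    seed = seed)
  simulate_cohort(cfg)
}

# Random clumping instance shared by the oracle-equivalence tests.
random_clump_instance <- function(seed, m = NULL, n = 40) {
  set.seed(seed)
  if (is.null(m)) m <- sample(2:20, 1)
  # blocky genotypes so r2 has a mix of high and low values
  base <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), n, m, byrow = TRUE)
  for (j in 2:m) {
    if (runif(1) < 0.5) base[, j] <- ifelse(runif(n) < 0.8, base[, j - 1], base[, j])
  }
  colnames(base) <- sprintf("v%02d", 1:m)
  variants <- data.frame(variant_id = colnames(base),
                         chrom = sample(c("1", "2"), m, replace = TRUE),
                         pos = sample.int(3e6, m), stringsAsFactors = FALSE)
  assoc <- data.frame(variant_id = colnames(base), beta = rnorm(m),
                      se = runif(m, 0.05, 0.2), p = runif(m)^3,
                      stringsAsFactors = FALSE)
  # drop monomorphic columns (LD undefined)
  poly <- apply(base, 2, sd) > 0
  list(assoc = assoc[poly, ], variants = variants[poly, ],
       dosage = base[, poly, drop = FALSE])
}
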