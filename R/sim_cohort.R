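#' Simulate demographic covariates for a pediatric cohort
#'
#' Ages are uniform over 5-20 years; sex is balanced; children recruited from
#' the obesity clinic (a configurable fraction of the cohort) draw BMI-SDS
#' from Normal(2.8, 0.75) and the remainder from Normal(0, 1). Pubertal
#' status is a logistic function of age (free parameter, centered at 11
#' years), plasma storage time is uniform over 0-10 years and PC1 is a
#' standard-normal stand-in for the leading genetic principal component.
#'
#' @param config a [sim_config()].
#' @return data.frame with sample_id, age, sex, bmi_sds, obesity, puberty,
#'   storage, pc1.
#' @export
simulate_covariates <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "covariates"))
  n <- config$n_samples
  age <- stats::runif(n, 5, 20)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "female", "male")
  obesity <- stats::rbinom(n, 1, config$obese_fraction)
  bmi_sds <- ifelse(obesity == 1,
                    stats::rnorm(n, 2.8, 0.75),
                    stats::rnorm(n, 0, 1))
  puberty <- stats::rbinom(n, 1, stats::plogis(0.9 * (age - 11)))
  storage <- stats::runif(n, 0, 10)
  pc1 <- stats::rnorm(n)
  data.frame(sample_id = sprintf("S%05d", seq_len(n)),
             age = age, sex = sex, bmi_sds = bmi_sds, obesity = obesity,
             puberty = puberty, storage = storage, pc1 = pc1,
             stringsAsFactors = FALSE)
}

#' Simulate Hardy-Weinberg genotypes with optional LD blocks
#'
#' Each variant draws a minor allele frequency uniformly from the configured
#' range and two haplotypes per sample under Hardy-Weinberg equilibrium. LD
#' is a first-order copy chain: with probability `ld_decay` a haplotype
#' copies its allele at the previous variant instead of drawing fresh, so
#' `ld_decay = 1` yields identical columns (r-squared 1) and `ld_decay = 0`
#' independent variants.
#'
#' Variants are laid on chromosomes in blocks of 100 at 50-kb spacing.
#' Planted-effect variants inherit consequence annotations when the effect
#' carries an amino-acid position (missense) and gene identifiers from their
#' target protein.
#'
#' @param config a [sim_config()].
#' @return list with `dosage` (samples x variants, values 0/1/2) and
#'   `variants` data.frame (variant_id, chrom, pos, ref, alt, maf,
#'   consequence, gene_id, aa_pos).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "genotypes"))
  n <- config$n_samples
  m <- config$n_variants
  maf <- if (is.null(config$maf_fixed)) {
    stats::runif(m, config$maf_range[1], config$maf_range[2])
  } else config$maf_fixed

  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  h1[, 1] <- stats::rbinom(n, 1, maf[1])
  h2[, 1] <- stats::rbinom(n, 1, maf[1])
  if (m > 1) {
    for (j in 2:m) {
      copy1 <- stats::rbinom(n, 1, config$ld_decay) == 1L
      copy2 <- stats::rbinom(n, 1, config$ld_decay) == 1L
      fresh1 <- stats::rbinom(n, 1, maf[j])
      fresh2 <- stats::rbinom(n, 1, maf[j])
      h1[, j] <- ifelse(copy1, h1[, j - 1], fresh1)
      h2[, j] <- ifelse(copy2, h2[, j - 1], fresh2)
      # a copied column tracks its neighbour's allele frequency
      if (config$ld_decay > 0) maf[j] <- config$ld_decay * maf[j - 1] + (1 - config$ld_decay) * maf[j]
    }
  }
  dosage <- h1 + h2
  storage.mode(dosage) <- "integer"

  per_chrom <- 100L
  chrom <- as.character((seq_len(m) - 1L) %/% per_chrom + 1L)
  pos <- ((seq_len(m) - 1L) %% per_chrom) * 50000L + 100000L
  # alt alleles avoid the ref complement: strand-ambiguous (palindromic)
  # SNPs are excluded by array QC upstream of any analysis
  bases <- c("A", "C", "G", "T")
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, c(r, compl[[r]])), 1L),
                character(1))

  variants <- data.frame(variant_id = sprintf("var%05d", seq_len(m)),
                         chrom = chrom, pos = pos, ref = ref, alt = alt,
                         maf = maf, consequence = "intergenic",
                         gene_id = NA_character_, aa_pos = NA_integer_,
                         stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("S%05d", seq_len(n))
  colnames(dosage) <- variants$variant_id
  for (pe in config$planted_effects) {
    if (!is.na(pe$aa_pos)) {
      variants$consequence[pe$variant] <- "missense"
      variants$aa_pos[pe$variant] <- pe$aa_pos
    }
    variants$gene_id[pe$variant] <- sprintf("GENE%04d", pe$protein)
  }
  list(dosage = dosage, variants = variants)
}

#' Simulate protein and peptide intensity matrices
#'
#' Log2 protein intensity = protein-specific baseline + planted genetic
#' effects (beta per alternate-allele dosage) + demographic covariate effects
#' + Normal noise. Each peptide tracks its parent protein with a fixed
#' peptide-specific offset plus peptide-level noise. Artefact peptides are
#' additionally attenuated on the linear scale by (2 - dosage)/2, so
#' homozygous-alternate carriers lose the peptide entirely: the mechanism by
#' which a protein-altering variant creates a dose-dependent, peptide-only
#' association. Missing-not-at-random dropout is then applied via a logistic
#' model on log2 intensity.
#'
#' @param config a [sim_config()].
#' @param genotypes result of [simulate_genotypes()].
#' @param covariates result of [simulate_covariates()].
#' @return list with `protein` and `peptide` observed matrices (NA =
#'   missing), `protein_complete`/`peptide_complete` pre-dropout matrices,
#'   `peptide_map` (peptide_id, protein_id, aa_start, aa_end) and
#'   `protein_info` (protein_id, gene_id, length).
#' @export
simulate_proteome <- function(config, genotypes, covariates) {
  validate_sim_config(config)
  n <- config$n_samples
  p <- config$n_proteins
  stopifnot(nrow(genotypes$dosage) == n, nrow(covariates) == n)
  set.seed(substream_seed(config$seed, "proteome"))

  baseline <- stats::rnorm(p, 20, 2)
  cm <- config$covariate_model
  beta_age <- stats::rnorm(p, 0, cm$age)
  beta_sex <- stats::rnorm(p, 0, cm$sex)
  beta_bmi <- stats::rnorm(p, 0, cm$bmi_sds)
  beta_obe <- stats::rnorm(p, 0, cm$obesity)
  beta_sto <- stats::rnorm(p, 0, cm$storage)
  sex_num <- as.integer(covariates$sex == "female")

  protein <- matrix(rep(baseline, each = n), n, p) +
    outer(covariates$age, beta_age) +
    outer(sex_num, beta_sex) +
    outer(covariates$bmi_sds, beta_bmi) +
    outer(covariates$obesity, beta_obe) +
    outer(covariates$storage, beta_sto) +
    matrix(stats::rnorm(n * p, 0, config$noise_sd_protein), n, p)
  for (pe in config$planted_effects) {
    if (pe$kind %in% c("cis", "trans") && pe$beta != 0) {
      protein[, pe$protein] <- protein[, pe$protein] +
        pe$beta * genotypes$dosage[, pe$variant]
    }
  }
  protein_ids <- sprintf("PROT%04d", seq_len(p))
  dimnames(protein) <- list(covariates$sample_id, protein_ids)

  n_pep <- sample(seq(config$peptides_per_protein[1], config$peptides_per_protein[2]),
                  p, replace = TRUE)
  pep_protein <- rep(seq_len(p), n_pep)
  pep_within <- unlist(lapply(n_pep, seq_len))
  # disjoint 15-mer tryptic spans every 40 residues
  aa_start <- (pep_within - 1L) * 40L + 11L
  aa_end <- aa_start + 14L
  peptide_map <- data.frame(
    peptide_id = sprintf("%s_pep%02d", protein_ids[pep_protein], pep_within),
    protein_id = protein_ids[pep_protein],
    aa_start = aa_start, aa_end = aa_end, stringsAsFactors = FALSE)

  k <- nrow(peptide_map)
  pep_offset <- stats::runif(k, -2, 0)
  peptide <- protein[, pep_protein, drop = FALSE] +
    matrix(rep(pep_offset, each = n), n, k) +
    matrix(stats::rnorm(n * k, 0, config$noise_sd_peptide), n, k)
  colnames(peptide) <- peptide_map$peptide_id

  for (pe in config$planted_effects) {
    if (pe$kind == "artefact") {
      idx <- which(pep_protein == pe$protein & pep_within == pe$artefact_peptide)
      if (length(idx) != 1L) {
        stop("artefact effect references peptide ", pe$artefact_peptide,
             " of protein ", pe$protein, " which does not exist")
      }
      d <- genotypes$dosage[, pe$variant]
      peptide[, idx] <- peptide[, idx] + log2((2 - d) / 2)  # dosage 2 -> -Inf
      # place the substitution inside this peptide's span
      peptide_map$aa_start[idx] <- pe$aa_pos - 7L
      peptide_map$aa_end[idx] <- pe$aa_pos + 7L
    }
  }
  peptide[!is.finite(peptide)] <- NA_real_

  protein_obs <- apply_mnar(protein, config$missingness)
  peptide_obs <- apply_mnar(peptide, config$missingness)

  list(protein = protein_obs, peptide = peptide_obs,
       protein_complete = protein, peptide_complete = peptide,
       peptide_map = peptide_map,
       protein_info = data.frame(protein_id = protein_ids,
                                 gene_id = sprintf("GENE%04d", seq_len(p)),
                                 length = n_pep * 40L + 20L,
                                 stringsAsFactors = FALSE))
}

#' Apply logistic missing-not-at-random dropout to a log2 intensity matrix
#'
#' P(missing) = plogis(intercept + slope * intensity); with a negative slope,
#' lower-abundance measurements drop out more often.
#'
#' @param mat numeric matrix of log2 intensities.
#' @param missingness list with `intercept` and `slope`.
#' @return matrix with additional NA entries.
#' @export
apply_mnar <- function(mat, missingness) {
  p_miss <- stats::plogis(missingness$intercept + missingness$slope * mat)
  drop <- matrix(stats::runif(length(mat)) < p_miss, nrow(mat), ncol(mat))
  mat[drop] <- NA_real_
  mat
}

#' Assemble a complete synthetic cohort bundle
#'
#' Runs covariate, genotype and proteome simulation and assembles the result
#' in the container every downstream stage consumes. Genes encoding proteins
#' with a planted cis effect are placed 50 kb from their variant (same
#' chromosome); all other genes sit far from every simulated variant so any
#' association with them is trans by construction. Trans-effect genes are
#' forced onto a different chromosome than their variant.
#'
#' @param config a [sim_config()].
#' @return a `cohort_bundle`: list with dosage, variants, protein, peptide,
#'   protein_complete, peptide_complete, peptide_map, gene_map, covariates,
#'   config.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  covariates <- simulate_covariates(config)
  genotypes <- simulate_genotypes(config)
  proteome <- simulate_proteome(config, genotypes, covariates)

  p <- config$n_proteins
  n_chrom <- max(as.integer(genotypes$variants$chrom))
  gene_map <- data.frame(gene_id = sprintf("GENE%04d", seq_len(p)),
                         protein_id = sprintf("PROT%04d", seq_len(p)),
                         chrom = as.character((seq_len(p) - 1L) %% n_chrom + 1L),
                         tss = 20000000L + 1000000L * seq_len(p),
                         strand = "+", stringsAsFactors = FALSE)
  for (pe in config$planted_effects) {
    v <- genotypes$variants[pe$variant, ]
    if (pe$kind %in% c("cis", "artefact")) {
      gene_map$chrom[pe$protein] <- v$chrom
      gene_map$tss[pe$protein] <- v$pos + 50000L
    } else if (pe$kind == "trans") {
      gene_map$chrom[pe$protein] <- as.character(as.integer(v$chrom) %% n_chrom + 1L)
    }
  }

  structure(list(dosage = genotypes$dosage, variants = genotypes$variants,
                 protein = proteome$protein, peptide = proteome$peptide,
                 protein_complete = proteome$protein_complete,
                 peptide_complete = proteome$peptide_complete,
                 peptide_map = proteome$peptide_map, gene_map = gene_map,
                 covariates = covariates, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Cohort bundle\n")
  cat(sprintf("  %d samples, %d variants, %d proteins, %d peptides\n",
              nrow(x$dosage), ncol(x$dosage), ncol(x$protein), ncol(x$peptide)))
  comp <- mean(!is.na(x$protein))
  cat(sprintf("  protein data completeness: %.1f%%\n", 100 * comp))
  invisible(x)
}

#' Simulate an independent outcome GWAS for two-sample Mendelian randomization
#'
#' Draws a fresh sample from the same generative model (the two-sample MR
#' assumption), constructs a quantitative trait as `theta` times the chosen
#' protein plus noise, and computes per-variant OLS summary statistics.
#'
#' @param config a [sim_config()]; a fresh cohort is drawn from a distinct
#'   substream of its seed.
#' @param theta causal effect of the protein on the trait (finite).
#' @param protein_index which protein drives the trait.
#' @param noise_sd SD of trait noise; 0 gives trait = theta * protein.
#' @param variants optional discovery variant table; when given, the outcome
#'   cohort is genotyped at the same variants (same alleles and population
#'   frequencies), as required for harmonizing the two samples.
#' @return summary-statistics data.frame (variant_id, chrom, pos,
#'   effect_allele, other_allele, eaf, beta, se, pval, n).
#' @export
simulate_outcome_gwas <- function(config, theta, protein_index = 1L,
                                  noise_sd = 1, variants = NULL) {
  if (!is.finite(theta)) stop("theta must be finite")
  cfg2 <- config
  cfg2$seed <- substream_seed(config$seed, "outcome-cohort")
  if (!is.null(variants)) cfg2$maf_fixed <- pmin(pmax(variants$maf, 1e-4), 0.5)
  covariates <- simulate_covariates(cfg2)
  genotypes <- simulate_genotypes(cfg2)
  if (!is.null(variants)) {
    genotypes$variants$ref <- variants$ref
    genotypes$variants$alt <- variants$alt
  }
  proteome <- simulate_proteome(cfg2, genotypes, covariates)
  set.seed(substream_seed(config$seed, "outcome-trait"))
  trait <- theta * proteome$protein_complete[, protein_index] +
    stats::rnorm(cfg2$n_samples, 0, noise_sd)
  scan <- assoc_scan(genotypes$dosage, trait)
  data.frame(variant_id = genotypes$variants$variant_id,
             chrom = genotypes$variants$chrom,
             pos = genotypes$variants$pos,
             effect_allele = genotypes$variants$alt,
             other_allele = genotypes$variants$ref,
             eaf = colMeans(genotypes$dosage) / 2,
             beta = scan$beta, se = scan$se, pval = scan$p,
             n = scan$n, stringsAsFactors = FALSE)
}
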