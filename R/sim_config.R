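#' Describe one planted genetic effect
#'
#' A planted effect links a simulated variant to a simulated protein. `cis`
#' and `trans` effects act on the protein itself (per alternate-allele dosage
#' on the log2 scale); an `artefact` effect leaves the protein untouched and
#' instead attenuates one variant-spanning peptide in proportion to
#' alternate-allele dosage, emulating the detectability artefact created when
#' a protein-altering variant removes a tryptic peptide from the searchable
#' sequence space while only the reference peptide is quantified.
#'
#' @param variant integer index of the variant (1-based).
#' @param protein integer index of the protein (1-based).
#' @param beta effect per alternate-allele dosage on the log2 protein scale.
#'   Must be 0 for `kind = "artefact"`: the artefact is peptide-only.
#' @param kind one of "cis", "trans", "artefact".
#' @param artefact_peptide for artefacts, which peptide of the protein (index
#'   within the protein's peptides) spans the variant residue.
#' @param aa_pos 1-based amino-acid position of the encoded substitution;
#'   required for artefacts.
#' @return a `planted_effect` list.
#' @export
planted_effect <- function(variant, protein, beta, kind = c("cis", "trans", "artefact"),
                           artefact_peptide = NULL, aa_pos = NULL) {
  kind <- match.arg(kind)
  if (kind == "artefact") {
    if (is.null(artefact_peptide) || is.null(aa_pos)) {
      stop("artefact effects require `artefact_peptide` and `aa_pos`")
    }
    if (beta != 0) stop("artefact effects must have beta = 0 on the protein itself")
  }
  structure(list(variant = as.integer(variant), protein = as.integer(protein),
                 beta = beta, kind = kind,
                 artefact_peptide = if (is.null(artefact_peptide)) NA_integer_ else as.integer(artefact_peptide),
                 aa_pos = if (is.null(aa_pos)) NA_integer_ else as.integer(aa_pos)),
            class = "planted_effect")
}

#' Configuration for a synthetic pediatric cohort
#'
#' Defaults emulate the structure of a school-age discovery cohort: ages 5-20,
#' roughly half of the children recruited from an obesity clinic (obese group
#' with BMI-SDS centered near +2.8), Hardy-Weinberg genotypes with optional
#' first-order LD blocks, log2-normal protein intensities driven by planted
#' genetic effects plus demographic covariates, peptides derived from their
#' parent protein, and abundance-dependent (missing-not-at-random)
#' missingness tuned so overall data completeness is around 90%.
#'
#' @param n_samples number of children in the cohort.
#' @param n_variants number of biallelic SNPs.
#' @param n_proteins number of quantified proteins.
#' @param peptides_per_protein length-2 integer range; each protein draws its
#'   peptide count uniformly from this range.
#' @param maf_range minor-allele-frequency range, each in (0, 0.5].
#' @param maf_fixed optional vector of per-variant allele frequencies
#'   overriding the uniform draw; used to give replication cohorts the same
#'   population allele frequencies as their discovery cohort.
#' @param ld_decay probability that an adjacent variant copies its
#'   neighbour's alleles (first-order copy chain; 0 = independent variants,
#'   1 = identical columns).
#' @param planted_effects list of [planted_effect()] objects.
#' @param covariate_model named list of per-covariate effect SDs on log2
#'   protein scale: `age`, `sex`, `bmi_sds`, `obesity`, `storage`. Each
#'   protein draws its coefficient from Normal(0, sd). Zero silences a term.
#' @param missingness named list `list(intercept=, slope=)` for the logistic
#'   missingness model on log2 intensity; a negative slope makes low-abundance
#'   measurements more likely to be missing (MNAR).
#' @param noise_sd_protein residual SD of log2 protein intensities.
#' @param noise_sd_peptide additional residual SD of log2 peptide intensities
#'   around their parent protein.
#' @param obese_fraction fraction of the cohort recruited from the obesity
#'   clinic.
#' @param seed integer root seed; every stage derives a named substream.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_samples = 500L,
                       n_variants = 500L,
                       n_proteins = 200L,
                       peptides_per_protein = c(2L, 8L),
                       maf_range = c(0.05, 0.5),
                       maf_fixed = NULL,
                       ld_decay = 0,
                       planted_effects = list(),
                       covariate_model = list(age = 0.02, sex = 0.1, bmi_sds = 0.05,
                                              obesity = 0.05, storage = 0.02),
                       missingness = list(intercept = 7.5, slope = -0.5),
                       noise_sd_protein = 1,
                       noise_sd_peptide = 0.5,
                       obese_fraction = 0.55,
                       seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_variants = as.integer(n_variants),
              n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              maf_range = as.numeric(maf_range),
              maf_fixed = if (is.null(maf_fixed)) NULL else as.numeric(maf_fixed),
              ld_decay = as.numeric(ld_decay),
              planted_effects = planted_effects, covariate_model = covariate_model,
              missingness = missingness,
              noise_sd_protein = as.numeric(noise_sd_protein),
              noise_sd_peptide = as.numeric(noise_sd_peptide),
              obese_fraction = as.numeric(obese_fraction),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 2L || n_variants < 1L || n_proteins < 1L) {
      stop("cohort dimensions must be positive (n_samples >= 2)")
    }
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2]) {
      stop("maf_range must be an increasing pair within (0, 0.5]")
    }
    if (ld_decay < 0 || ld_decay > 1) stop("ld_decay must lie in [0, 1]")
    if (!is.null(maf_fixed)) {
      if (length(maf_fixed) != n_variants || any(maf_fixed <= 0) || any(maf_fixed > 0.5)) {
        stop("maf_fixed must give one frequency in (0, 0.5] per variant")
      }
    }
    if (noise_sd_protein < 0 || noise_sd_peptide < 0) stop("noise SDs must be >= 0")
    if (obese_fraction < 0 || obese_fraction > 1) stop("obese_fraction must lie in [0, 1]")
    if (length(peptides_per_protein) != 2L || any(peptides_per_protein < 1L) ||
        peptides_per_protein[1] > peptides_per_protein[2]) {
      stop("peptides_per_protein must be an increasing pair of positive counts")
    }
    for (pe in planted_effects) {
      if (!inherits(pe, "planted_effect")) stop("planted_effects entries must be planted_effect objects")
      if (pe$variant < 1L || pe$variant > n_variants) {
        stop("planted effect references variant index out of range: ", pe$variant)
      }
      if (pe$protein < 1L || pe$protein > n_proteins) {
        stop("planted effect references protein index out of range: ", pe$protein)
      }
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  samples: %d  variants: %d  proteins: %d\n",
              x$n_samples, x$n_variants, x$n_proteins))
  cat(sprintf("  MAF range: [%.3f, %.3f]  ld_decay: %.2f  planted effects: %d\n",
              x$maf_range[1], x$maf_range[2], x$ld_decay, length(x$planted_effects)))
  cat(sprintf("  noise SD (protein/peptide): %.2f/%.2f  seed: %d\n",
              x$noise_sd_protein, x$noise_sd_peptide, x$seed))
  invisible(x)
}
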