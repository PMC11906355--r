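# Shared setup for the numbered analysis scripts: argument parsing, paths
# and the study-design constants used across stages.
suppressMessages(library(pedpqtl))

parse_seed <- function(default = 1L) {
  args <- commandArgs(trailingOnly = TRUE)
  i <- match("--seed", args)
  if (!is.na(i)) as.integer(args[i + 1L]) else default
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(dirname(d), recursive = TRUE, showWarnings = FALSE)
  d
}

# Discovery-cohort design: a pediatric cohort with planted genetic effects
# covering the cases the downstream stages must distinguish — strong and
# moderate cis effects, a trans effect, and a peptide-detectability artefact.
study_config <- function(seed) {
  sim_config(
    n_samples = 800L, n_variants = 300L, n_proteins = 60L,
    peptides_per_protein = c(3L, 8L), ld_decay = 0.3,
    # demographic signal strong enough that a protein panel tracks age and
    # adiposity, as observed in pediatric plasma proteomes
    covariate_model = list(age = 0.05, sex = 0.12, bmi_sds = 0.08,
                           obesity = 0.06, storage = 0.02),
    planted_effects = list(
      planted_effect(20L, 1L, 1.5, "cis"),
      planted_effect(60L, 2L, 1.0, "cis"),
      planted_effect(110L, 3L, 0.8, "cis"),
      planted_effect(160L, 4L, 0.9, "trans"),
      planted_effect(210L, 5L, 0, "artefact", artefact_peptide = 1L, aa_pos = 30L),
      planted_effect(260L, 6L, 0, "artefact", artefact_peptide = 2L, aa_pos = 70L)),
    seed = seed)
}
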