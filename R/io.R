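#' Read a biallelic-SNP VCF into a dosage matrix
#'
#' Accepts VCF 4.x with a GT field; "0/0", "0/1", "1/1" (and phased "|"
#' variants) map to dosages 0, 1, 2; "./." to missing. Multi-allelic records
#' are rejected with their record identifiers.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return list with `dosage` (samples x variants integer matrix) and
#'   `variants` data.frame (variant_id, chrom, pos, ref, alt).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF comes back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic records not supported: ",
         paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi])), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt_norm <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt_norm), ncol(gt_norm), dimnames = dimnames(gt_norm))
  dos[gt_norm %in% c("0/0")] <- 0L
  dos[gt_norm %in% c("0/1", "1/0")] <- 1L
  dos[gt_norm %in% c("1/1")] <- 2L
  bad <- !is.na(gt_norm) & !(gt_norm %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt_norm[bad][1], "' at record ", rownames(gt_norm)[idx[1]])
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  dosage <- t(dos)
  colnames(dosage) <- variants$variant_id
  list(dosage = dosage, variants = variants)
}

#' Write a dosage matrix as a minimal VCF (v4.2, GT only)
#'
#' @param dosage samples x variants matrix in {0,1,2}, NA = missing.
#' @param variants variant table with variant_id, chrom, pos, ref, alt.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dosage, variants, path) {
  stopifnot(ncol(dosage) == nrow(variants))
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(j) {
    g <- dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_codes[g + 1L])
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read/write sample-by-feature intensity matrices as TSV
#'
#' First column `sample_id`, remaining columns features; missing values are
#' empty fields, never zero. Round-trips values at 15 significant digits.
#'
#' @param path TSV path.
#' @return numeric matrix with sample_id rownames.
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          skip = n_comment_lines(path))
  if (names(dt)[1] != "sample_id") stop("matrix TSV must start with a sample_id column")
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- dt[[1]]
  m
}

#' @rdname read_matrix_tsv
#' @param mat samples x features matrix with rownames.
#' @param header optional comment lines (e.g. a config-hash stamp) written
#'   before the table, each prefixed with "#".
#' @export
write_matrix_tsv <- function(mat, path, header = NULL) {
  dt <- data.table::data.table(sample_id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  write_with_header(dt, path, header)
}

# "#"-prefixed provenance lines above a fwrite'd table
write_with_header <- function(dt, path, header) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE,
                       append = TRUE, col.names = TRUE)
  } else {
    data.table::fwrite(dt, path, sep = "\t", na = "", quote = FALSE)
  }
  invisible(path)
}

# number of leading comment lines in a text table
n_comment_lines <- function(path) {
  head_lines <- readLines(path, n = 100L)
  sum(cumprod(startsWith(head_lines, "#")))
}

SUMMARY_STATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                        "other_allele", "eaf", "beta", "se", "pval", "n")

#' Read/write GWAS summary statistics in the pipeline's fixed schema
#'
#' Columns: variant_id, chrom, pos, effect_allele, other_allele, eaf, beta,
#' se, pval, n.
#'
#' @param path TSV path.
#' @return data.frame in schema order.
#' @export
read_summary_stats <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "",
                          skip = n_comment_lines(path))
  missing_cols <- setdiff(SUMMARY_STATS_COLS, names(dt))
  if (length(missing_cols) > 0) {
    stop("summary statistics missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  as.data.frame(dt)[, SUMMARY_STATS_COLS]
}

#' @rdname read_summary_stats
#' @param stats data.frame containing at least the schema columns.
#' @param header optional "#"-prefixed comment lines.
#' @export
write_summary_stats <- function(stats, path, header = NULL) {
  missing_cols <- setdiff(SUMMARY_STATS_COLS, names(stats))
  if (length(missing_cols) > 0) {
    stop("summary statistics missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  write_with_header(data.table::as.data.table(stats[, SUMMARY_STATS_COLS]),
                    path, header)
}

#' Read gene annotations from a BED-like file and derive 1-based TSS
#'
#' BED uses 0-based half-open coordinates; the transcription start site is
#' the 1-based start for "+"-strand genes and the end coordinate for
#' "-"-strand genes.
#'
#' @param path BED path with columns chrom, start, end, gene_id, score,
#'   strand (score ignored).
#' @return data.frame with gene_id, chrom, tss (1-based), strand.
#' @export
read_gene_bed <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 6L) stop("gene BED requires chrom, start, end, name, score and strand columns")
  data.table::setnames(dt, 1:6, c("chrom", "start", "end", "gene_id", "score", "strand"))
  tss <- ifelse(dt$strand == "-", dt$end, dt$start + 1L)
  data.frame(gene_id = dt$gene_id, chrom = as.character(dt$chrom),
             tss = as.integer(tss), strand = dt$strand, stringsAsFactors = FALSE)
}

#' Read a covariate table
#'
#' @param path TSV with sample_id, age, sex, bmi_sds, obesity, puberty,
#'   storage, pc1.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "")
  req <- c("sample_id", "age", "sex", "bmi_sds", "obesity")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols) > 0) {
    stop("covariate table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  as.data.frame(dt)
}

#' Write a cohort bundle to a directory of standard files
#'
#' Emits genotypes as VCF, protein/peptide matrices, peptide map, variant
#' annotation and covariates as TSV, and genes as BED (converting the
#' internal 1-based TSS back to 0-based half-open intervals). Every table is
#' stamped with the configuration hash.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- paste0("config_hash: ", config_hash(bundle$config))
  write_vcf(bundle$dosage, bundle$variants, file.path(dir, "genotypes.vcf"))
  write_matrix_tsv(bundle$protein, file.path(dir, "protein.tsv"), header = stamp)
  write_matrix_tsv(bundle$peptide, file.path(dir, "peptide.tsv"), header = stamp)
  data.table::fwrite(bundle$peptide_map, file.path(dir, "peptide_map.tsv"), sep = "\t")
  data.table::fwrite(bundle$variants, file.path(dir, "variants.tsv"), sep = "\t", na = "")
  data.table::fwrite(bundle$covariates, file.path(dir, "covariates.tsv"), sep = "\t", na = "")
  bed <- data.frame(chrom = bundle$gene_map$chrom,
                    start = bundle$gene_map$tss - 1L,
                    end = bundle$gene_map$tss,
                    gene_id = bundle$gene_map$gene_id,
                    score = 0L, strand = bundle$gene_map$strand)
  data.table::fwrite(bed, file.path(dir, "genes.bed"), sep = "\t", col.names = FALSE)
  invisible(dir)
}

#' Load a cohort bundle from a directory of standard files
#'
#' Aligns every matrix to the covariate table's sample order and fails if
#' any sample set differs.
#'
#' @param dir directory written by [write_cohort()] (or assembled by hand in
#'   the same layout).
#' @return a `cohort_bundle` (without simulation-only complete matrices).
#' @export
read_cohort <- function(dir) {
  geno <- read_vcf(file.path(dir, "genotypes.vcf"))
  protein <- read_matrix_tsv(file.path(dir, "protein.tsv"))
  peptide <- read_matrix_tsv(file.path(dir, "peptide.tsv"))
  peptide_map <- as.data.frame(data.table::fread(file.path(dir, "peptide_map.tsv")))
  variants <- as.data.frame(data.table::fread(file.path(dir, "variants.tsv"), na.strings = ""))
  covariates <- read_covariates(file.path(dir, "covariates.tsv"))
  genes <- read_gene_bed(file.path(dir, "genes.bed"))

  ids <- covariates$sample_id
  for (nm in list(list("genotypes", rownames(geno$dosage)),
                  list("protein matrix", rownames(protein)),
                  list("peptide matrix", rownames(peptide)))) {
    if (!setequal(nm[[2]], ids)) stop("sample identifiers differ between covariates and ", nm[[1]])
  }
  unknown <- setdiff(peptide_map$protein_id, colnames(protein))
  if (length(unknown) > 0) {
    stop("peptides map to proteins absent from the protein matrix: ",
         paste(utils::head(unknown), collapse = ", "))
  }
  if (any(variants$pos <= 0)) stop("non-positive genomic positions in variant table")
  if (any(variants$ref == variants$alt)) stop("ref equals alt for some variants")

  # gene_id encodes the protein index in the simulated layout; a real
  # deployment would supply an explicit protein-to-gene table instead
  gm <- genes
  gm$protein_id <- sub("^GENE", "PROT", gm$gene_id)
  structure(list(dosage = geno$dosage[ids, , drop = FALSE],
                 variants = merge_variant_annotation(geno$variants, variants),
                 protein = protein[ids, , drop = FALSE],
                 peptide = peptide[ids, , drop = FALSE],
                 peptide_map = peptide_map, gene_map = gm,
                 covariates = covariates,
                 config = list(seed = NA_integer_)),
            class = "cohort_bundle")
}

merge_variant_annotation <- function(vcf_variants, annot) {
  idx <- match(vcf_variants$variant_id, annot$variant_id)
  out <- vcf_variants
  out$maf <- annot$maf[idx]
  out$consequence <- annot$consequence[idx]
  out$gene_id <- annot$gene_id[idx]
  out$aa_pos <- annot$aa_pos[idx]
  out
}
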