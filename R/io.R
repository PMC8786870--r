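# Reading and writing of the pipeline's table formats: genotype TSV or
# minimal VCF, phenotype CSV, annotation CSV. Every written file carries a
# comment header with package version, seed and config hash; readers skip
# comment lines.

.file_header <- function(seed = NA, config_hash = NA) {
  c(sprintf("# grsbmi %s", as.character(packageVersion("grsbmi"))),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", config_hash))
}

.write_table <- function(x, path, sep, seed = NA, config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(seed, config_hash), con)
  write.table(x, con, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write / read a genotype dosage TSV
#'
#' Rows are subjects, columns SNP identifiers, cells 0/1/2 or NA; the first
#' column \code{subject_id} holds the subject identifier.
#'
#' @param genotypes subjects x SNPs integer matrix.
#' @param path output file.
#' @param seed,config_hash recorded in the header comment.
#' @return the path, invisibly (writer); dosage matrix (reader).
#' @export
write_genotypes <- function(genotypes, path, seed = NA, config_hash = NA) {
  df <- data.frame(subject_id = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_table(df, path, sep = "\t", seed = seed, config_hash = config_hash)
}

#' @rdname write_genotypes
#' @param dialect \code{"tsv"} or \code{"vcf"}.
#' @param annotation required for VCF input: per-SNP effect/other alleles
#'   used to orient ALT counts into effect-allele dosages.
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"),
                           annotation = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(.read_genotypes_vcf(path, annotation))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "subject_id") stop("first column must be subject_id")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in genotypes")
  g <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(g))) stop("duplicate SNP identifiers")
  if (any(!is.na(g) & !(g %in% c(0, 1, 2))))
    stop("genotype dosages must be 0, 1, 2 or NA")
  storage.mode(g) <- "integer"
  rownames(g) <- df$subject_id
  g
}

.read_genotypes_vcf <- function(path, annotation) {
  if (is.null(annotation)) stop("VCF input needs an annotation table")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))                       # single-record VCF
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT)))
    stop("multi-allelic VCF site(s): ",
         paste(fix$ID[grepl(",", fix$ALT)], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  alt_count[clean == "0/0"] <- 0L
  alt_count[clean %in% c("0/1", "1/0")] <- 1L
  alt_count[clean == "1/1"] <- 2L
  ann <- annotation[match(fix$ID, annotation$snp_id), ]
  if (anyNA(ann$snp_id))
    stop("VCF SNP(s) missing from annotation: ",
         paste(fix$ID[is.na(ann$snp_id)], collapse = ", "))
  eff_is_alt <- ann$effect_allele == fix$ALT & ann$other_allele == fix$REF
  eff_is_ref <- ann$effect_allele == fix$REF & ann$other_allele == fix$ALT
  if (any(!eff_is_alt & !eff_is_ref))
    stop("allele mismatch between VCF and annotation for: ",
         paste(fix$ID[!eff_is_alt & !eff_is_ref], collapse = ", "))
  dos <- alt_count
  dos[eff_is_ref, ] <- 2L - alt_count[eff_is_ref, , drop = FALSE]
  out <- t(dos)
  colnames(out) <- fix$ID
  out
}

#' Write a minimal biallelic VCF (GT field only)
#'
#' One record per SNP with REF = other allele, ALT = effect allele, and
#' unphased GT genotypes; the dosage is the effect-allele count.
#'
#' @param genotypes effect-allele dosage matrix.
#' @param annotation annotation with snp_id, chr, pos, effect/other alleles.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(genotypes, annotation, path) {
  ann <- annotation[match(colnames(genotypes), annotation$snp_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=grsbmi %s", packageVersion("grsbmi")),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(genotypes)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(ann$chr[j], ann$pos[j], ann$snp_id[j],
                       ann$other_allele[j], ann$effect_allele[j], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read the phenotype table
#'
#' CSV with columns subject_id, depression (0/1), bmi, sex (0/1), age,
#' province. The reader validates types and uniqueness.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @param seed,config_hash header metadata.
#' @export
write_pheno <- function(pheno, path, seed = NA, config_hash = NA) {
  .write_table(pheno, path, sep = ",", seed = seed, config_hash = config_hash)
}

#' @rdname write_pheno
#' @export
read_pheno <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("subject_id", "bmi", "sex", "age", "province")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in phenotype")
  if (!is.numeric(df$bmi) || any(!is.na(df$bmi) & df$bmi <= 0))
    stop("bmi must be positive numeric")
  if ("depression" %in% names(df) && !all(df$depression %in% c(0, 1)))
    stop("depression must be 0/1")
  if (!all(df$sex %in% c(0, 1))) stop("sex must be 0/1")
  df$province <- factor(df$province)
  df
}

#' Write / read the SNP annotation table
#'
#' CSV with snp_id, chr, pos, effect_allele, other_allele,
#' literature_direction (+1/-1), source.
#'
#' @param annotation annotation data.frame.
#' @param path file path.
#' @param seed,config_hash header metadata.
#' @export
write_annotation <- function(annotation, path, seed = NA, config_hash = NA) {
  .write_table(annotation, path, sep = ",", seed = seed,
               config_hash = config_hash)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("snp_id", "effect_allele", "other_allele", "literature_direction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$snp_id)) stop("duplicate snp_id in annotation")
  if (!all(df$literature_direction %in% c(-1, 1)))
    stop("literature_direction must be +1 or -1")
  class(df) <- c("snp_annotation", "data.frame")
  df
}
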