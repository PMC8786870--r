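# End-to-end orchestration: simulate (or load) -> QC -> univariate scan ->
# concordance selection -> GRS -> risk models -> model evaluation, with a
# manifest of stage-wise counts.

#' Hash of a configuration object
#'
#' MD5 of the JSON serialisation; recorded in output headers and the run
#' manifest so a run's provenance is checkable.
#'
#' @param config any jsonlite-serialisable object.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full GRS pipeline
#'
#' Executes, in order: data acquisition (simulation with the given settings,
#' or reading the three input files), quality control, the univariate SNP
#' scan on depression, concordance selection against the literature
#' directions, risk-allele orientation, complete-case GRS construction,
#' quartile assignment, the quartile and interaction risk models, and the
#' five-model evaluation suite (plus optional cross-validation). Outputs are
#' written under \code{out_dir} when given; a manifest of stage-wise counts
#' is always returned and identical config + seed reproduce identical
#' outputs.
#'
#' @param config list. Either \code{simulate = list(...)} (arguments of
#'   \code{\link{simulate_study}}) or paths \code{geno}, \code{pheno},
#'   \code{annotation} (with optional \code{geno_dialect}). Optional
#'   entries: \code{qc} (arguments of \code{\link{qc_config}}),
#'   \code{cuts}, \code{cv = list(k =, enabled =)}, \code{seed},
#'   \code{out_dir}.
#' @return list of class \code{run_result}: \code{manifest}, \code{qc},
#'   \code{scan}, \code{concordance}, \code{grs}, \code{quartile_model},
#'   \code{interaction}, \code{suite}, \code{cv} (or NULL), \code{data}
#'   (the analysis table).
#' @export
run_all <- function(config = list()) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cuts <- if (is.null(config$cuts)) c(0.05, 0.25) else config$cuts
  hash <- config_hash(config)

  if (!is.null(config$geno)) {
    annotation <- read_annotation(config$annotation)
    geno <- read_genotypes(config$geno,
                           dialect = if (is.null(config$geno_dialect)) "tsv"
                                     else config$geno_dialect,
                           annotation = annotation)
    pheno <- read_pheno(config$pheno)
    if (!setequal(rownames(geno), pheno$subject_id))
      stop("genotype and phenotype subject sets differ")
    geno <- geno[pheno$subject_id, , drop = FALSE]
  } else {
    sim <- do.call(simulate_study,
                   c(config$simulate, list(seed = seed)))
    geno <- sim$genotypes; pheno <- sim$pheno; annotation <- sim$annotation
  }
  n0 <- nrow(pheno); m0 <- ncol(geno)

  qc_cfg <- do.call(qc_config, if (is.null(config$qc)) list() else config$qc)
  qc <- run_qc(geno, pheno, qc_cfg)

  scan <- univariate_snp_scan(qc$genotypes, qc$pheno, outcome = "depression")
  conc <- concordance_select(scan[!scan$skipped, ], annotation)
  selected <- conc$snp_id[conc$concordant]
  if (length(selected) == 0) stop("no concordant SNPs: GRS undefined")

  risk <- orient_to_risk(qc$genotypes, annotation, selected)
  grs <- compute_grs(risk)
  grs$quartile <- assign_quartiles(grs$grs)

  dat <- merge(qc$pheno, grs, by = "subject_id")
  quart <- grs_quartile_contrasts(dat)
  inter <- interaction_model(dat)
  suite <- evaluate_model_suite(dat, cuts = cuts)
  cv <- NULL
  if (!is.null(config$cv) && isTRUE(config$cv$enabled)) {
    k <- if (is.null(config$cv$k)) 5 else config$cv$k
    cv <- kfold_cv(dat, k = k, seed = seed, cuts = cuts)
  }

  manifest <- list(
    package_version = as.character(packageVersion("grsbmi")),
    seed = seed, config_hash = hash, timestamp = format(Sys.time()),
    counts = c(subjects_in = n0, subjects_after_qc = nrow(qc$pheno),
               subjects_grs = nrow(grs),
               subjects_dropped_bmi = n0 - nrow(qc$pheno),
               subjects_dropped_missing_geno = attr(grs, "n_dropped"),
               snps_in = m0, snps_after_qc = ncol(qc$genotypes),
               snps_selected = length(selected)))
  stopifnot(manifest$counts["subjects_after_qc"] ==
              manifest$counts["subjects_grs"] +
              manifest$counts["subjects_dropped_missing_geno"])

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(f) file.path(config$out_dir, f)
    write_genotypes(qc$genotypes, wp("genotypes_qc.tsv"), seed, hash)
    .write_table(qc$snp_qc, wp("snp_qc_report.tsv"), "\t", seed, hash)
    .write_table(conc, wp("concordance_selection.csv"), ",", seed, hash)
    .write_table(grs, wp("grs.csv"), ",", seed, hash)
    .write_table(inter$grid, wp("interaction_grid.csv"), ",", seed, hash)
    .write_table(cbind(comparison = rownames(reclass_table(suite)),
                       reclass_table(suite)),
                 wp("model_improvement.tsv"), "\t", seed, hash)
    jsonlite::write_json(
      list(manifest = manifest, auc = suite$auc,
           quartile_contrasts = quart$contrasts,
           interaction = inter$interaction),
      wp("summary.json"), auto_unbox = TRUE, digits = NA, force = TRUE,
      dataframe = "rows")
  }
  structure(list(manifest = manifest, qc = qc, scan = scan,
                 concordance = conc, grs = grs, quartile_model = quart,
                 interaction = inter, suite = suite, cv = cv, data = dat),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("GRS pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  print(x$manifest$counts)
  cat("\n")
  print(x$interaction)
  cat("\nAUC by model:\n")
  print(format(x$suite$auc, digits = 3), row.names = FALSE)
  invisible(x)
}
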