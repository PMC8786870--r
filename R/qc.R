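# Marker- and subject-level quality control: BMI exclusion, call rate,
# minor allele frequency, Hardy-Weinberg exact test in controls, and
# greedy LD pruning on genotype R^2.

#' QC thresholds
#'
#' @param call_rate_min minimum SNP call rate (SNPs with call rate strictly
#'   below are excluded), default 0.95.
#' @param maf_min minimum minor-allele frequency, default 0.05 (exclusion is
#'   strict: MAF below the threshold fails).
#' @param hwe_alpha significance level of the Hardy-Weinberg exact test in
#'   controls, default 0.05.
#' @param ld_r2_max maximum tolerated pairwise genotype R^2; pairs above it
#'   are pruned, default 0.8.
#' @param bmi_min_exclusive subjects with BMI less than or equal to this are
#'   excluded (underweight), default 18.5.
#' @param drop_hwe_failures if TRUE (default) SNPs failing HWE are excluded;
#'   if FALSE they are only flagged in the QC report.
#' @return list of class \code{qc_config}.
#' @export
qc_config <- function(call_rate_min = 0.95, maf_min = 0.05, hwe_alpha = 0.05,
                      ld_r2_max = 0.8, bmi_min_exclusive = 18.5,
                      drop_hwe_failures = TRUE) {
  stopifnot(call_rate_min > 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5,
            hwe_alpha > 0, hwe_alpha < 1,
            ld_r2_max > 0, ld_r2_max <= 1)
  structure(list(call_rate_min = call_rate_min, maf_min = maf_min,
                 hwe_alpha = hwe_alpha, ld_r2_max = ld_r2_max,
                 bmi_min_exclusive = bmi_min_exclusive,
                 drop_hwe_failures = drop_hwe_failures),
            class = "qc_config")
}

#' SNP call rate
#'
#' Fraction of non-missing genotypes in a dosage column.
#'
#' @param dosage vector of dosages 0/1/2 with NA for missing.
#' @return proportion in [0, 1].
#' @export
call_rate <- function(dosage) {
  if (length(dosage) == 0) stop("empty dosage column")
  mean(!is.na(dosage))
}

#' Minor allele frequency
#'
#' Allele frequency of the less common allele, computed over non-missing
#' dosages (dosage = count of one allele, so its frequency is
#' \code{mean(dosage)/2}); a tie at 0.5 returns 0.5.
#'
#' @param dosage vector of dosages 0/1/2 with NA for missing.
#' @return proportion in [0, 0.5].
#' @export
minor_allele_freq <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  if (length(dosage) == 0) stop("all genotypes missing")
  f <- mean(dosage) / 2
  min(f, 1 - f)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg genotype proportions conditional on
#' the observed allele counts: the p-value is the sum of the conditional
#' probabilities of every heterozygote count no more probable than the
#' observed one (Wigginton-style exact test). Probabilities are accumulated
#' with the standard heterozygote recurrence on the log scale for stability.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("total genotype count must be >= 1")
  # rare allele count; invariant under swapping AA <-> aa
  nr <- 2 * min(n_AA, n_aa) + n_Aa
  if (nr == 0) return(1)
  hets <- seq.int(nr %% 2, nr, by = 2)          # admissible het counts
  # log unnormalised conditional probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_hom_r(h) * n_hom_c(h) / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    hom_r <- (nr - h) / 2                        # rare homozygotes at h
    hom_c <- n - (h + hom_r)                     # common homozygotes at h
    lp[k] <- lp[k - 1L] + log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  obs <- match(n_Aa, hets)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Pairwise genotype R-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' subjects (unphased, composite LD measure). If either column is constant on
#' the pairwise-complete subset the statistic is undefined: \code{NA} is
#' returned with a warning and the pair is treated as not prunable.
#'
#' @param dosage_i,dosage_j dosage vectors of equal length.
#' @return R^2 in [0, 1], or NA for a constant column.
#' @export
ld_r2 <- function(dosage_i, dosage_j) {
  ok <- !is.na(dosage_i) & !is.na(dosage_j)
  if (sum(ok) < 2) stop("need >= 2 pairwise-complete subjects")
  x <- dosage_i[ok]; y <- dosage_j[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant dosage column: LD R^2 undefined, pair not prunable")
    return(NA_real_)
  }
  cor(x, y)^2
}

#' Run genotype and phenotype quality control
#'
#' Applies, in order: (1) exclusion of underweight subjects
#' (BMI <= \code{bmi_min_exclusive}); (2) SNP call-rate filter; (3) MAF
#' filter; (4) Hardy-Weinberg exact test in controls at \code{hwe_alpha}
#' (flag, and exclusion when \code{drop_hwe_failures}); (5) greedy LD
#' pruning: SNP pairs (in column order) with R^2 > \code{ld_r2_max} lose the
#' member with the lower call rate, ties dropping the later column.
#'
#' @param genotypes subjects x SNPs dosage matrix (rownames = subject ids).
#' @param pheno phenotype data.frame with \code{subject_id}, \code{bmi} and,
#'   if available, \code{depression} (used to restrict the HWE test to
#'   controls; without it all subjects are used, with a warning).
#' @param config a \code{\link{qc_config}}.
#' @return list of class \code{qc_result}: \code{genotypes}, \code{pheno}
#'   (filtered), \code{snp_qc} (per-SNP audit data.frame with reason codes),
#'   \code{subjects_dropped}, and stage-wise \code{counts}.
#' @export
run_qc <- function(genotypes, pheno, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  if (!identical(rownames(genotypes), pheno$subject_id))
    stop("genotypes and pheno refer to different subjects")
  n0 <- nrow(pheno); m0 <- ncol(genotypes)

  keep_subj <- pheno$bmi > config$bmi_min_exclusive
  pheno2 <- pheno[keep_subj, , drop = FALSE]
  geno2 <- genotypes[keep_subj, , drop = FALSE]

  cr <- apply(geno2, 2, call_rate)
  maf <- apply(geno2, 2, function(x)
    if (all(is.na(x))) NA_real_ else minor_allele_freq(x))

  if ("depression" %in% names(pheno2)) {
    ctrl <- geno2[pheno2$depression == 0, , drop = FALSE]
  } else {
    warning("no depression column: HWE test uses all subjects")
    ctrl <- geno2
  }
  hwe_p <- apply(ctrl, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })

  fail_cr <- cr < config$call_rate_min
  fail_maf <- !fail_cr & (is.na(maf) | maf < config$maf_min)
  fail_hwe <- !fail_cr & !fail_maf & !is.na(hwe_p) & hwe_p < config$hwe_alpha
  alive <- !(fail_cr | fail_maf | (config$drop_hwe_failures & fail_hwe))

  # greedy LD pruning among survivors, column order, drop lower call rate
  pruned <- rep(FALSE, m0)
  idx <- which(alive)
  if (length(idx) >= 2) {
    for (a in seq_len(length(idx) - 1L)) {
      i <- idx[a]
      if (pruned[i]) next
      for (b in seq.int(a + 1L, length(idx))) {
        j <- idx[b]
        if (pruned[j]) next
        r2 <- suppressWarnings(ld_r2(geno2[, i], geno2[, j]))
        if (!is.na(r2) && r2 > config$ld_r2_max) {
          drop <- if (cr[i] < cr[j]) i else j   # tie -> later column j
          pruned[drop] <- TRUE
          if (drop == i) break
        }
      }
    }
  }
  alive <- alive & !pruned

  reasons <- mapply(function(c1, c2, c3, c4) {
    r <- c(if (c1) "call_rate", if (c2) "maf",
           if (c3 && config$drop_hwe_failures) "hwe", if (c4) "ld_pruned")
    if (length(r)) paste(r, collapse = ";") else ""
  }, fail_cr, fail_maf, fail_hwe, pruned)

  snp_qc <- data.frame(snp_id = colnames(genotypes), call_rate = cr,
                       maf = maf, hwe_p_controls = hwe_p,
                       hwe_fail = fail_hwe, ld_pruned = pruned,
                       pass = alive, reason = reasons,
                       row.names = NULL, stringsAsFactors = FALSE)

  geno3 <- geno2[, alive, drop = FALSE]
  if (nrow(geno3) == 0 || ncol(geno3) == 0)
    stop(sprintf(paste0("QC removed everything (subjects %d -> %d, ",
                        "SNPs %d -> %d)"), n0, nrow(geno3), m0, ncol(geno3)))
  structure(list(genotypes = geno3, pheno = pheno2, snp_qc = snp_qc,
                 subjects_dropped = pheno$subject_id[!keep_subj],
                 counts = c(subjects_in = n0, subjects_out = nrow(pheno2),
                            snps_in = m0, snps_out = ncol(geno3),
                            snps_fail_call_rate = sum(fail_cr),
                            snps_fail_maf = sum(fail_maf),
                            snps_fail_hwe = sum(fail_hwe),
                            snps_ld_pruned = sum(pruned))),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Genotype/phenotype QC\n")
  cat(sprintf("  subjects: %d -> %d (BMI exclusion: %d)\n",
              x$counts["subjects_in"], x$counts["subjects_out"],
              length(x$subjects_dropped)))
  cat(sprintf(paste0("  SNPs: %d -> %d (call rate %d, MAF %d, HWE %d,",
                     " LD pruned %d)\n"),
              x$counts["snps_in"], x$counts["snps_out"],
              x$counts["snps_fail_call_rate"], x$counts["snps_fail_maf"],
              x$counts["snps_fail_hwe"], x$counts["snps_ld_pruned"]))
  invisible(x)
}
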