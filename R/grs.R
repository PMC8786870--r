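# Concordance-based SNP selection, risk-allele orientation and the
# unweighted genetic risk score with the complete-case rule.

#' Concordance screen against literature effect directions
#'
#' Compares the fitted per-allele log-odds of each SNP (from the univariate
#' scan) with its literature effect direction. A SNP is concordant when the
#' fitted sign equals the literature sign; statistical significance is NOT
#' required — the score deliberately pools small, individually non-significant
#' effects. Exactly-zero fitted betas count as discordant.
#'
#' @param univariate_results data.frame with columns \code{snp_id},
#'   \code{beta} and (optionally) \code{p} — e.g. the output of
#'   \code{\link{univariate_snp_scan}}.
#' @param annotation annotation table with \code{snp_id} and
#'   \code{literature_direction}.
#' @return data.frame of class \code{concordance_records}: snp_id, fitted
#'   beta and p, literature_direction, concordant flag. The selected panel is
#'   \code{subset(x, concordant)$snp_id}.
#' @export
concordance_select <- function(univariate_results, annotation) {
  miss <- setdiff(univariate_results$snp_id, annotation$snp_id)
  if (length(miss))
    stop("SNP(s) missing from annotation: ", paste(miss, collapse = ", "))
  dir <- annotation$literature_direction[
    match(univariate_results$snp_id, annotation$snp_id)]
  beta <- univariate_results$beta
  out <- data.frame(snp_id = univariate_results$snp_id,
                    fitted_beta = beta,
                    fitted_p = if ("p" %in% names(univariate_results))
                      univariate_results$p else NA_real_,
                    literature_direction = dir,
                    concordant = !is.na(beta) & beta != 0 &
                      sign(beta) == dir,
                    stringsAsFactors = FALSE)
  class(out) <- c("concordance_records", "data.frame")
  out
}

#' Orient dosages to risk-allele counts
#'
#' Dosages count the effect (minor) allele. SNPs whose minor allele is
#' reported protective in the literature are flipped (\code{g -> 2 - g}) so
#' every column counts risk alleles; risk-direction SNPs are unchanged and
#' missing genotypes stay missing.
#'
#' @param genotypes subjects x SNPs dosage matrix.
#' @param annotation annotation with \code{snp_id} and
#'   \code{literature_direction}.
#' @param selected_snps character vector of SNP ids to keep (default: all
#'   columns).
#' @return risk-allele-count matrix over \code{selected_snps}.
#' @export
orient_to_risk <- function(genotypes, annotation,
                           selected_snps = colnames(genotypes)) {
  if (!all(selected_snps %in% colnames(genotypes)))
    stop("selected SNPs absent from genotype matrix")
  g <- genotypes[, selected_snps, drop = FALSE]
  if (any(!is.na(g) & !(g %in% c(0, 1, 2))))
    stop("dosages must be 0, 1, 2 or missing")
  dir <- annotation$literature_direction[
    match(selected_snps, annotation$snp_id)]
  if (anyNA(dir))
    stop("selected SNP(s) missing from annotation: ",
         paste(selected_snps[is.na(dir)], collapse = ", "))
  flip <- dir < 0
  g[, flip] <- 2 - g[, flip]
  g
}

#' Unweighted genetic risk score
#'
#' Sums risk-allele counts over the selected SNPs with the complete-case
#' rule: subjects missing any genotype among the selected panel are removed
#' (the score is undefined for them), and the number removed is reported.
#'
#' @param risk_matrix oriented risk-allele-count matrix from
#'   \code{\link{orient_to_risk}}.
#' @param selected_snps SNP ids to sum over (default: all columns).
#' @return data.frame of class \code{grs_result}: subject_id, grs (integer).
#'   Attributes: \code{"snp_set"} (ordered SNP ids used), \code{"n_dropped"}
#'   and \code{"dropped_subjects"}.
#' @export
compute_grs <- function(risk_matrix, selected_snps = colnames(risk_matrix)) {
  if (length(selected_snps) == 0) stop("empty SNP set")
  if (!all(selected_snps %in% colnames(risk_matrix)))
    stop("selected SNPs absent from risk matrix")
  g <- risk_matrix[, selected_snps, drop = FALSE]
  complete <- rowSums(is.na(g)) == 0
  out <- data.frame(subject_id = rownames(g)[complete],
                    grs = as.integer(rowSums(g[complete, , drop = FALSE])),
                    stringsAsFactors = FALSE)
  attr(out, "snp_set") <- selected_snps
  attr(out, "n_dropped") <- sum(!complete)
  attr(out, "dropped_subjects") <- rownames(g)[!complete]
  class(out) <- c("grs_result", "data.frame")
  out
}

#' Assign risk-score quartiles
#'
#' Cut-points are the sample quartiles (type-7 quantiles, linear
#' interpolation); a value equal to a cut-point goes to the lower stratum.
#' Labels Q1..Q4 in ascending risk, Q1 being the reference stratum in
#' downstream contrasts.
#'
#' @param grs_values numeric vector of risk scores (>= 4 values).
#' @return factor with levels Q1..Q4.
#' @export
assign_quartiles <- function(grs_values) {
  if (length(grs_values) < 4) stop("need at least 4 subjects")
  q <- quantile(grs_values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(q)) < 3)
    warning("quartile cut-points are tied: ",
            "quartile contrasts may be degenerate")
  # value equal to a cut-point goes to the lower stratum
  idx <- rowSums(outer(grs_values, q, ">")) + 1L
  factor(paste0("Q", idx), levels = paste0("Q", 1:4))
}
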