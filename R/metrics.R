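# Discrimination and reclassification metrics: ROC AUC with DeLong
# inference (via pROC), and IDI / categorical NRI / category-free NRI with
# Pencina-style asymptotic standard errors (optional percentile bootstrap).

.check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 (control) / 1 (case)")
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1)
    stop("need at least one case and one control")
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC in the Mann-Whitney formulation — the probability that a random case
#' scores above a random control, ties counting one half — with a 95\%
#' DeLong CI.
#'
#' @param scores numeric risk scores or probabilities.
#' @param labels 0/1 vector (1 = case).
#' @return list: auc, ci (length 2).
#' @export
roc_auc <- function(scores, labels) {
  .check_labels(labels)
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- tryCatch(suppressWarnings(
    as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  list(auc = as.numeric(pROC::auc(r)), ci = ci)
}

#' DeLong paired test for two correlated AUCs
#'
#' Two-sided DeLong test comparing the AUCs of two score vectors on the same
#' subjects. Identical score vectors give a zero difference and p = 1.
#'
#' @param scores_old,scores_new paired score vectors.
#' @param labels 0/1 vector.
#' @return list: auc_old, auc_new, delta, p.
#' @export
compare_auc <- function(scores_old, scores_new, labels) {
  if (length(scores_old) != length(scores_new) ||
      length(scores_old) != length(labels))
    stop("scores and labels must be paired on identical subjects")
  .check_labels(labels)
  a0 <- roc_auc(scores_old, labels)$auc
  a1 <- roc_auc(scores_new, labels)$auc
  if (isTRUE(all.equal(scores_old, scores_new)))
    return(list(auc_old = a0, auc_new = a1, delta = 0, p = 1))
  r0 <- pROC::roc(labels, scores_old, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  r1 <- pROC::roc(labels, scores_new, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  p <- tryCatch(pROC::roc.test(r0, r1, method = "delong",
                               paired = TRUE)$p.value,
                error = function(e) NA_real_)
  if (is.nan(p)) p <- 1
  list(auc_old = a0, auc_new = a1, delta = a1 - a0, p = unname(p))
}

.asymp <- function(est, se) {
  if (!is.finite(se) || se == 0)
    return(list(est = est, ci = c(NA_real_, NA_real_), p = NA_real_))
  list(est = est, ci = est + c(-1, 1) * qnorm(0.975) * se,
       p = 2 * pnorm(-abs(est / se)))
}

.boot_ci <- function(stat, labels, p_old, p_new, B, seed) {
  set.seed(seed)
  ca <- which(labels == 1); co <- which(labels == 0)
  reps <- vapply(seq_len(B), function(b) {
    i <- c(sample(ca, replace = TRUE), sample(co, replace = TRUE))
    stat(labels[i], p_old[i], p_new[i])
  }, numeric(1))
  unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
}

#' Integrated discrimination improvement
#'
#' \eqn{IDI = (\bar{p}_{new} - \bar{p}_{old} | cases) -
#' (\bar{p}_{new} - \bar{p}_{old} | controls)}: the gain in discrimination
#' slope of the new model over the old. Inference is an asymptotic z-test
#' from the standard errors of the per-group risk differences; a stratified
#' percentile bootstrap CI is available instead.
#'
#' @param labels 0/1 vector (1 = case).
#' @param p_old,p_new predicted probabilities under the old and new model.
#' @param boot use a stratified percentile bootstrap CI (default FALSE).
#' @param B,seed bootstrap replicates and seed.
#' @return list: est, ci, p.
#' @export
idi <- function(labels, p_old, p_new, boot = FALSE, B = 500, seed = 1L) {
  .check_labels(labels)
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop("need >= 2 cases and >= 2 controls")
  d <- p_new - p_old
  dc <- d[labels == 1]; dn <- d[labels == 0]
  est <- mean(dc) - mean(dn)
  se <- sqrt(var(dc) / length(dc) + var(dn) / length(dn))
  out <- .asymp(est, se)
  if (boot)
    out$ci <- .boot_ci(function(l, po, pn)
      mean(pn[l == 1] - po[l == 1]) - mean(pn[l == 0] - po[l == 0]),
      labels, p_old, p_new, B, seed)
  out
}

.risk_category <- function(p, cuts) {
  findInterval(p, cuts, left.open = FALSE) # [0,c1) [c1,c2) [c2,1]
}

.nri_core <- function(labels, up, down) {
  nc <- sum(labels == 1); nn <- sum(labels == 0)
  puc <- mean(up[labels == 1]); pdc <- mean(down[labels == 1])
  pun <- mean(up[labels == 0]); pdn <- mean(down[labels == 0])
  est <- (puc - pdc) + (pdn - pun)
  se <- sqrt((puc + pdc) / nc - (puc - pdc)^2 / nc +
             (pun + pdn) / nn - (pdn - pun)^2 / nn)
  .asymp(est, se)
}

#' Categorical net reclassification improvement
#'
#' Risk categories are \code{[0, cuts[1])}, \code{[cuts[1], cuts[2])},
#' \code{[cuts[2], 1]} (defaults 5\% and 25\%: low / medium / high, the
#' boundary belonging to the upper category). NRI = net proportion of cases
#' reclassified upward plus net proportion of controls reclassified
#' downward; ranges over [-2, 2].
#'
#' @inheritParams idi
#' @param cuts strictly increasing risk cut-points in (0, 1).
#' @return list: est, ci, p (p is NA when nobody moves).
#' @export
categorical_nri <- function(labels, p_old, p_new, cuts = c(0.05, 0.25),
                            boot = FALSE, B = 500, seed = 1L) {
  .check_labels(labels)
  if (any(diff(cuts) <= 0) || any(cuts <= 0 | cuts >= 1))
    stop("cuts must be strictly increasing within (0, 1)")
  c_old <- .risk_category(p_old, cuts)
  c_new <- .risk_category(p_new, cuts)
  out <- .nri_core(labels, c_new > c_old, c_new < c_old)
  if (boot)
    out$ci <- .boot_ci(function(l, po, pn) {
      a <- .risk_category(po, cuts); b <- .risk_category(pn, cuts)
      .nri_core(l, b > a, b < a)$est
    }, labels, p_old, p_new, B, seed)
  out
}

#' Category-free net reclassification improvement
#'
#' Any increase in predicted risk counts as upward movement and any decrease
#' as downward; combined as in \code{\link{categorical_nri}}.
#'
#' @inheritParams idi
#' @return list: est, ci, p.
#' @export
category_free_nri <- function(labels, p_old, p_new, boot = FALSE, B = 500,
                              seed = 1L) {
  .check_labels(labels)
  out <- .nri_core(labels, p_new > p_old, p_new < p_old)
  if (boot)
    out$ci <- .boot_ci(function(l, po, pn)
      .nri_core(l, pn > po, pn < po)$est,
      labels, p_old, p_new, B, seed)
  out
}
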