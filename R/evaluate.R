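# Evaluation of the five nested risk models: in-sample AUC / NRI / cfNRI /
# IDI for the canonical model comparisons, and stratified k-fold
# cross-validation.

.canonical_comparisons <- list(c(1, 2), c(1, 3), c(3, 4), c(3, 5), c(4, 5))

#' Pairwise model-improvement report
#'
#' Bundles, for one old/new model pair evaluated on the same subjects: both
#' AUCs with DeLong CIs and the paired DeLong p-value, the categorical NRI
#' at the given risk cuts, the category-free NRI, and the IDI, each with CI
#' and p-value.
#'
#' @param labels 0/1 outcome (1 = case).
#' @param p_old,p_new predicted probabilities of the initial and final model.
#' @param cuts risk-category cut-points for the categorical NRI.
#' @param boot use bootstrap CIs for NRI/cfNRI/IDI.
#' @param B,seed bootstrap settings.
#' @return object of class \code{reclass_report}.
#' @export
reclass_report <- function(labels, p_old, p_new, cuts = c(0.05, 0.25),
                           boot = FALSE, B = 500, seed = 1L) {
  aucs <- compare_auc(p_old, p_new, labels)
  structure(list(auc_old = roc_auc(p_old, labels),
                 auc_new = roc_auc(p_new, labels),
                 delta_auc = aucs$delta, delta_auc_p = aucs$p,
                 nri = categorical_nri(labels, p_old, p_new, cuts,
                                       boot = boot, B = B, seed = seed),
                 cfnri = category_free_nri(labels, p_old, p_new,
                                           boot = boot, B = B, seed = seed),
                 idi = idi(labels, p_old, p_new, boot = boot, B = B,
                           seed = seed),
                 cuts = cuts, n = length(labels)),
            class = "reclass_report")
}

#' @export
print.reclass_report <- function(x, ...) {
  fmt <- function(m) sprintf("%+.4f (%.4f, %.4f), p = %.3g",
                             m$est, m$ci[1], m$ci[2], m$p)
  cat(sprintf("AUC %.3f -> %.3f (DeLong p = %.3g)\n",
              x$auc_old$auc, x$auc_new$auc, x$delta_auc_p))
  cat("  NRI   ", fmt(x$nri), "\n")
  cat("  cfNRI ", fmt(x$cfnri), "\n")
  cat("  IDI   ", fmt(x$idi), "\n")
  invisible(x)
}

#' Fit and compare the five nested risk models
#'
#' Fits Models 1-5 (\code{\link{model_formula}}) on the complete-case
#' intersection of all model terms, computes in-sample predicted
#' probabilities, and evaluates the canonical comparisons
#' 1-2, 1-3, 3-4, 3-5 and 4-5 with AUC/NRI/cfNRI/IDI.
#'
#' @param data data.frame with depression, sex, age, province, bmi, grs.
#' @param comparisons list of old/new model-id pairs; default the canonical
#'   five.
#' @param cuts NRI risk cut-points.
#' @param boot,B,seed bootstrap settings for the reclassification CIs.
#' @return object of class \code{model_suite}: \code{fits} (list of
#'   \code{grs_fit}), \code{probs} (n x 5 matrix), \code{auc}
#'   (per-model data.frame), \code{comparisons} (named list of
#'   \code{reclass_report}), \code{n}.
#' @export
evaluate_model_suite <- function(data, comparisons = .canonical_comparisons,
                                 cuts = c(0.05, 0.25), boot = FALSE,
                                 B = 500, seed = 1L) {
  vars <- c("depression", "sex", "age", "province", "bmi", "grs")
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, vars]), vars]
  fits <- lapply(1:5, function(m) fit_glm(d, model_formula(m), "logistic"))
  probs <- vapply(fits, function(f) unname(predict(f$glm, type = "response")),
                  numeric(nrow(d)))
  colnames(probs) <- paste0("model", 1:5)
  auc <- do.call(rbind, lapply(1:5, function(m) {
    a <- roc_auc(probs[, m], d$depression)
    data.frame(model = m, auc = a$auc, ci_lo = a$ci[1], ci_hi = a$ci[2],
               d_squared = fits[[m]]$d_squared)
  }))
  comp <- lapply(comparisons, function(cc)
    reclass_report(d$depression, probs[, cc[1]], probs[, cc[2]], cuts = cuts,
                   boot = boot, B = B, seed = seed))
  names(comp) <- vapply(comparisons, function(cc)
    sprintf("m%d_to_m%d", cc[1], cc[2]), character(1))
  structure(list(fits = fits, probs = probs, auc = auc, comparisons = comp,
                 n = nrow(d)),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  cat(sprintf("Risk-model suite on %d subjects (%d cases)\n", x$n,
              sum(x$fits[[1]]$glm$y)))
  print(format(x$auc, digits = 3), row.names = FALSE)
  for (nm in names(x$comparisons)) {
    cat("\n", nm, ":\n", sep = "")
    print(x$comparisons[[nm]])
  }
  invisible(x)
}

#' Reclassification table in the shape of a model-comparison summary
#'
#' Rows NRI, NRI p, cfNRI, cfNRI p, IDI, IDI p; one column per comparison.
#'
#' @param suite a \code{\link{evaluate_model_suite}} result.
#' @return data.frame.
#' @export
reclass_table <- function(suite) {
  stopifnot(inherits(suite, "model_suite"))
  cols <- lapply(suite$comparisons, function(r)
    c(NRI = r$nri$est, `NRI p` = r$nri$p,
      cfNRI = r$cfnri$est, `cfNRI p` = r$cfnri$p,
      IDI = r$idi$est, `IDI p` = r$idi$p))
  as.data.frame(cols, check.names = FALSE)
}

#' Stratified k-fold cross-validation of the model suite
#'
#' Outcome-stratified folds (caret's fold construction); each fold is held
#' out once while Models 1-5 are fitted on the remaining folds and used to
#' predict it. Per-fold AUC (per model) and NRI/cfNRI/IDI point estimates
#' (per comparison) are averaged across folds with equal weights. The mean
#' out-of-fold AUC is reported next to the in-sample AUC so shrinkage
#' (optimism) is visible.
#'
#' @param data as in \code{\link{evaluate_model_suite}}.
#' @param k number of folds (default 5; must not exceed the case count).
#' @param seed fold-assignment seed.
#' @param comparisons,cuts as in \code{\link{evaluate_model_suite}}.
#' @return object of class \code{cv_report}: \code{k}, \code{seed},
#'   \code{folds} (test indices), \code{fold_auc} (k x 5),
#'   \code{auc} (fold-averaged per model, with in-sample for reference),
#'   \code{fold_metrics}, \code{metrics} (fold-averaged per comparison).
#' @export
kfold_cv <- function(data, k = 5, seed = 1L,
                     comparisons = .canonical_comparisons,
                     cuts = c(0.05, 0.25)) {
  vars <- c("depression", "sex", "age", "province", "bmi", "grs")
  d <- data[complete.cases(data[, vars]), vars]
  n_case <- sum(d$depression == 1)
  if (k > n_case) stop("k exceeds the number of cases")
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  folds <- caret::createFolds(factor(d$depression), k = k)
  if (any(vapply(folds, function(i) sum(d$depression[i]) == 0, logical(1))))
    stop("a fold has no cases; reduce k")
  oof <- matrix(NA_real_, nrow(d), 5, dimnames = list(NULL, paste0("model", 1:5)))
  fold_auc <- matrix(NA_real_, k, 5)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    for (m in 1:5) {
      fit <- fit_glm(d[-test, ], model_formula(m), "logistic")
      oof[test, m] <- predict(fit$glm, newdata = d[test, ], type = "response")
      fold_auc[f, m] <- roc_auc(oof[test, m], d$depression[test])$auc
    }
  }
  fold_metrics <- lapply(seq_len(k), function(f) {
    test <- folds[[f]]
    lab <- d$depression[test]
    vapply(comparisons, function(cc) {
      po <- oof[test, cc[1]]; pn <- oof[test, cc[2]]
      c(nri = categorical_nri(lab, po, pn, cuts)$est,
        cfnri = category_free_nri(lab, po, pn)$est,
        idi = idi(lab, po, pn)$est,
        auc_old = roc_auc(po, lab)$auc, auc_new = roc_auc(pn, lab)$auc)
    }, numeric(5))
  })
  metrics <- Reduce(`+`, fold_metrics) / k
  colnames(metrics) <- vapply(comparisons, function(cc)
    sprintf("m%d_to_m%d", cc[1], cc[2]), character(1))
  in_sample <- evaluate_model_suite(d, comparisons = comparisons,
                                    cuts = cuts)$auc$auc
  structure(list(k = k, seed = seed, folds = folds, fold_auc = fold_auc,
                 auc = data.frame(model = 1:5,
                                  auc_oof = colMeans(fold_auc),
                                  auc_in_sample = in_sample),
                 fold_metrics = fold_metrics, metrics = metrics),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d)\n", x$k, x$seed))
  print(format(x$auc, digits = 3), row.names = FALSE)
  cat("\nFold-averaged reclassification metrics:\n")
  print(round(x$metrics, 4))
  invisible(x)
}
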