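# Regression layer: nested logistic risk models (Models 1-5), per-SNP
# scans with BH correction, quartile contrasts, the GRS-by-BMI interaction
# model, descriptive group comparisons, and post-hoc power.

#' Formula of a canonical risk model
#'
#' The five nested models evaluated by the pipeline:
#' Model 1 \code{depression ~ sex + age + province};
#' Model 2 adds \code{bmi}; Model 3 adds \code{grs} to Model 1;
#' Model 4 has both \code{grs} and \code{bmi} as marginal terms;
#' Model 5 replaces them with \code{grs * bmi} (marginals + product).
#'
#' @param model integer 1..5.
#' @return a formula.
#' @export
model_formula <- function(model) {
  switch(as.character(model),
         "1" = depression ~ sex + age + province,
         "2" = depression ~ sex + age + province + bmi,
         "3" = depression ~ sex + age + province + grs,
         "4" = depression ~ sex + age + province + grs + bmi,
         "5" = depression ~ sex + age + province + grs * bmi,
         stop("model must be 1..5"))
}

#' Fit a logistic or linear model with a full coefficient report
#'
#' Thin wrapper around \code{stats::glm} returning Wald inference per term
#' (estimate, SE, two-sided p, and for logistic fits the odds ratio with its
#' 95\% Wald CI), the deviance-based explained variation
#' \eqn{D^2 = 1 - deviance / null~deviance}, and convergence/separation
#' diagnostics. Complete cases on the model terms are used and counted.
#'
#' @param data data.frame holding every term of \code{formula}.
#' @param formula model formula; see \code{\link{model_formula}}.
#' @param family \code{"logistic"} (binomial-logit) or \code{"linear"}.
#' @return object of class \code{grs_fit} with elements \code{coefficients}
#'   (data.frame), \code{deviance}, \code{null_deviance}, \code{d_squared},
#'   \code{converged}, \code{separation}, \code{n_used}, \code{glm} (the
#'   underlying fit, for prediction).
#' @export
fit_glm <- function(data, formula, family = c("logistic", "linear")) {
  family <- match.arg(family)
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing model terms: ", paste(miss, collapse = ", "))
  data <- data[complete.cases(data[, vars, drop = FALSE]), , drop = FALSE]
  y <- data[[vars[1]]]
  if (family == "logistic" && !all(y %in% c(0, 1)))
    stop("logistic outcome must be 0/1")
  fam <- if (family == "logistic") binomial() else gaussian()
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = fam),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  tab <- data.frame(term = names(cf), estimate = unname(cf),
                    se = unname(se), p = unname(p),
                    stringsAsFactors = FALSE)
  if (family == "logistic") {
    tab$or <- exp(tab$estimate)
    tab$ci_lo <- exp(tab$estimate - qnorm(0.975) * tab$se)
    tab$ci_hi <- exp(tab$estimate + qnorm(0.975) * tab$se)
  } else {
    tab$ci_lo <- tab$estimate - qnorm(0.975) * tab$se
    tab$ci_hi <- tab$estimate + qnorm(0.975) * tab$se
  }
  separation <- sep_warn || any(is.na(cf)) ||
    any(abs(cf[-1]) > 10 & se[-1] > 10) || !fit$converged
  structure(list(coefficients = tab,
                 deviance = fit$deviance,
                 null_deviance = fit$null.deviance,
                 d_squared = max(0, 1 - fit$deviance / fit$null.deviance),
                 converged = fit$converged,
                 separation = separation,
                 n_used = nrow(data),
                 family = family, formula = formula, glm = fit),
            class = "grs_fit")
}

#' @export
print.grs_fit <- function(x, digits = 3, ...) {
  cat(deparse(x$formula), "  [", x$family, "]\n", sep = "")
  cat(sprintf("n = %d, D^2 = %.4f%s\n", x$n_used, x$d_squared,
              if (x$separation) "  ** possible separation **" else ""))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Per-SNP univariate association scan
#'
#' Fits one covariate-adjusted additive model per SNP: logistic for the
#' depression outcome, linear for BMI. Dosages enter as allele counts 0/1/2.
#' For the continuous outcome a normality gate (Shapiro-Wilk on the
#' residuals of the covariate-only model, at \code{shapiro_alpha}) triggers
#' the configured transformation of the outcome — natural log or rank-based
#' inverse-normal — before the scan. P-values are Benjamini-Hochberg
#' adjusted across the scanned SNPs. Monomorphic SNPs are skipped with a
#' reason code.
#'
#' @param genotypes dosage matrix (subjects x SNPs) aligned with
#'   \code{pheno}.
#' @param pheno data.frame with the outcome and adjustment covariates.
#' @param outcome \code{"depression"} or \code{"bmi"}.
#' @param adjust covariate names, default \code{c("sex","age","province")}.
#' @param transform transformation applied to a continuous outcome when the
#'   normality gate fires: \code{"int"} (rank-based inverse normal) or
#'   \code{"log"}.
#' @param shapiro_alpha gate level, default 0.05.
#' @return data.frame (class \code{snp_scan}): snp_id, n, beta, se, p,
#'   or/ci (logistic), p_adj, skipped, reason; attribute
#'   \code{"transform_applied"}.
#' @export
univariate_snp_scan <- function(genotypes, pheno,
                                outcome = c("depression", "bmi"),
                                adjust = c("sex", "age", "province"),
                                transform = c("int", "log"),
                                shapiro_alpha = 0.05) {
  outcome <- match.arg(outcome)
  transform <- match.arg(transform)
  if (!identical(rownames(genotypes), pheno$subject_id))
    stop("genotypes and pheno refer to different subjects")
  family <- if (outcome == "depression") "logistic" else "linear"
  dat <- pheno
  transform_applied <- "none"
  if (family == "linear") {
    base <- lm(as.formula(paste(outcome, "~",
                                paste(adjust, collapse = "+"))), data = dat)
    res <- stats::residuals(base)
    if (length(res) > 5000) res <- sample(res, 5000)
    if (shapiro.test(res)$p.value < shapiro_alpha) {
      dat[[outcome]] <- if (transform == "log") log(dat[[outcome]]) else
        rank_inverse_normal(dat[[outcome]])
      transform_applied <- transform
    }
  }
  fml <- as.formula(paste(outcome, "~ dosage +",
                          paste(adjust, collapse = "+")))
  rows <- lapply(colnames(genotypes), function(s) {
    dos <- genotypes[, s]
    if (length(unique(na.omit(dos))) < 2)
      return(data.frame(snp_id = s, n = sum(!is.na(dos)), beta = NA_real_,
                        se = NA_real_, p = NA_real_, or = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        skipped = TRUE, reason = "monomorphic",
                        stringsAsFactors = FALSE))
    d <- dat; d$dosage <- dos
    f <- fit_glm(d, fml, family = family)
    co <- f$coefficients[f$coefficients$term == "dosage", ]
    data.frame(snp_id = s, n = f$n_used, beta = co$estimate, se = co$se,
               p = co$p,
               or = if (family == "logistic") co$or else NA_real_,
               ci_lo = co$ci_lo, ci_hi = co$ci_hi,
               skipped = FALSE, reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !out$skipped
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "BH")
  attr(out, "transform_applied") <- transform_applied
  class(out) <- c("snp_scan", "data.frame")
  out
}

#' Rank-based inverse-normal transformation
#'
#' Blom-offset rank transform \code{qnorm((rank - 3/8) / (n + 1/4))}.
#'
#' @param x numeric vector without missing values.
#' @return transformed vector with the same order as \code{x}.
#' @export
rank_inverse_normal <- function(x) {
  qnorm((rank(x, ties.method = "average") - 3 / 8) / (length(x) + 1 / 4))
}

#' Quartile-contrast risk model
#'
#' Logistic model of depression on risk-score quartile (Q1 = reference)
#' plus adjustment covariates, reporting the Q2-, Q3- and Q4-vs-Q1 odds
#' ratios with Wald CIs and p-values.
#'
#' @param data data.frame with \code{depression}, \code{quartile} (factor
#'   Q1..Q4) and the adjustment covariates.
#' @param adjust covariates, default sex/age/province.
#' @return list: \code{fit} (\code{\link{fit_glm}} object) and
#'   \code{contrasts} (data.frame quartile/or/ci_lo/ci_hi/p).
#' @export
grs_quartile_contrasts <- function(data, adjust = c("sex", "age", "province")) {
  if (!"quartile" %in% names(data)) stop("data must carry a quartile column")
  tabq <- table(factor(data$quartile, levels = paste0("Q", 1:4)))
  if (any(tabq == 0))
    stop("empty quartile stratum: ",
         paste(names(tabq)[tabq == 0], collapse = ", "))
  fml <- as.formula(paste("depression ~ quartile +",
                          paste(adjust, collapse = "+")))
  fit <- fit_glm(data, fml, family = "logistic")
  co <- fit$coefficients
  co <- co[grepl("^quartileQ", co$term), ]
  contrasts <- data.frame(quartile = sub("^quartile", "", co$term),
                          or = co$or, ci_lo = co$ci_lo, ci_hi = co$ci_hi,
                          p = co$p, stringsAsFactors = FALSE)
  list(fit = fit, contrasts = contrasts)
}

#' GRS-by-BMI interaction model with prediction grid
#'
#' Fits Model 5 (\code{depression ~ sex + age + province + grs * bmi}) and
#' tabulates predicted depression probabilities over the observed GRS range
#' at BMI strata mean + \code{grid_sds} standard deviations, with the other
#' covariates held at their means (numeric) or reference level (factors) —
#' the standard display of an interaction profile.
#'
#' With \code{center = TRUE}, GRS and BMI enter centred at their sample
#' means: the product coefficient is unchanged, and the GRS main effect
#' becomes the per-allele effect at mean BMI (the interpretable scale on
#' which a per-allele odds ratio such as 1.35 is quoted).
#'
#' @param data data.frame with depression, grs, bmi and the adjustment
#'   covariates.
#' @param adjust covariates, default sex/age/province.
#' @param center centre grs and bmi before fitting (default FALSE).
#' @param grid_sds BMI strata in SD units, default \code{-2:2}.
#' @return list of class \code{interaction_fit}: \code{fit},
#'   \code{interaction} (one-row data.frame for the product term) and
#'   \code{grid} (grs, bmi_stratum, bmi, predicted_probability).
#' @export
interaction_model <- function(data, adjust = c("sex", "age", "province"),
                              center = FALSE, grid_sds = -2:2) {
  d <- data
  if (center) {
    d$grs <- d$grs - mean(d$grs)
    d$bmi <- d$bmi - mean(d$bmi)
  }
  fml <- as.formula(paste("depression ~", paste(adjust, collapse = "+"),
                          "+ grs * bmi"))
  fit <- fit_glm(d, fml, family = "logistic")
  inter <- fit$coefficients[fit$coefficients$term == "grs:bmi", ]

  grs_grid <- seq(min(d$grs), max(d$grs), length.out = 25)
  bmi_strata <- mean(d$bmi) + grid_sds * sd(d$bmi)
  new0 <- lapply(d[adjust], function(v)
    if (is.numeric(v)) mean(v) else factor(levels(v)[1], levels = levels(v)))
  grid <- expand.grid(grs = grs_grid, stratum = seq_along(grid_sds))
  nd <- cbind(as.data.frame(new0)[rep(1, nrow(grid)), , drop = FALSE],
              grs = grid$grs, bmi = bmi_strata[grid$stratum])
  rownames(nd) <- NULL
  grid_out <- data.frame(grs = grid$grs,
                         bmi_stratum = sprintf("%+d SD", grid_sds[grid$stratum]),
                         bmi = nd$bmi,
                         predicted_probability =
                           predict(fit$glm, newdata = nd, type = "response"),
                         stringsAsFactors = FALSE)
  structure(list(fit = fit, interaction = inter, grid = grid_out,
                 centered = center),
            class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat("GRS x BMI interaction model",
      if (x$centered) "(centred covariates)" else "(raw units)", "\n")
  cat(sprintf("  interaction OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$interaction$or, x$interaction$ci_lo, x$interaction$ci_hi,
              x$interaction$p))
  cat(sprintf("  model D^2 = %.4f, n = %d\n", x$fit$d_squared, x$fit$n_used))
  invisible(x)
}

#' Pooled-SD Cohen's d from group summaries
#'
#' \eqn{d = (m_1 - m_2) / s_p} with
#' \eqn{s_p^2 = ((n_1-1)s_1^2 + (n_2-1)s_2^2) / (n_1+n_2-2)}.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return Cohen's d (signed, group 1 minus group 2).
#' @export
cohens_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

#' Two-group comparison with effect size
#'
#' For a quantitative variable, compares two groups with Student's t,
#' Welch's t or the Mann-Whitney U test (\code{test = "auto"} picks
#' Mann-Whitney when either group fails a Shapiro-Wilk normality check at
#' 0.05, otherwise Student vs Welch by an F-test of equal variances) and
#' reports pooled-SD Cohen's d. For a contingency table (matrix input),
#' runs Pearson's chi-squared test and reports Cramér's V
#' \eqn{\sqrt{\chi^2 / (n (\min(r,c)-1))}}.
#'
#' @param x numeric vector of values, or a contingency matrix/table.
#' @param groups factor/vector with two levels (ignored for matrix input).
#' @param test \code{"auto"}, \code{"student_t"}, \code{"welch_t"} or
#'   \code{"mann_whitney"}.
#' @return list of class \code{effect_size_report}: test_used, p, and
#'   cohens_d or cramers_v.
#' @export
group_compare <- function(x, groups = NULL,
                          test = c("auto", "student_t", "welch_t",
                                   "mann_whitney")) {
  if (is.matrix(x) || is.table(x)) {
    m <- as.matrix(x)
    chi <- suppressWarnings(chisq.test(m, correct = FALSE))
    v <- sqrt(unname(chi$statistic) / (sum(m) * (min(dim(m)) - 1)))
    return(structure(list(test_used = "chi_squared",
                          p = unname(chi$p.value), cramers_v = v),
                     class = "effect_size_report"))
  }
  test <- match.arg(test)
  g <- factor(groups)
  if (nlevels(g) != 2) stop("need exactly two groups")
  xs <- split(x, g)
  n <- lengths(xs)
  if (any(n < 2)) stop("each group needs >= 2 observations")
  if (test == "auto") {
    norm_p <- vapply(xs, function(v) {
      if (length(v) > 5000) v <- sample(v, 5000)
      if (length(v) < 3 || sd(v) == 0) return(0)
      shapiro.test(v)$p.value
    }, numeric(1))
    if (any(norm_p < 0.05)) {
      test <- "mann_whitney"
    } else {
      vr <- stats::var.test(xs[[1]], xs[[2]])$p.value
      test <- if (vr < 0.05) "welch_t" else "student_t"
    }
  }
  p <- switch(test,
              student_t = t.test(xs[[1]], xs[[2]], var.equal = TRUE)$p.value,
              welch_t = t.test(xs[[1]], xs[[2]])$p.value,
              mann_whitney = suppressWarnings(
                wilcox.test(xs[[1]], xs[[2]])$p.value))
  d <- cohens_d_pooled(mean(xs[[1]]), sd(xs[[1]]), n[1],
                       mean(xs[[2]]), sd(xs[[2]]), n[2])
  structure(list(test_used = test, p = unname(p), cohens_d = unname(d)),
            class = "effect_size_report")
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("%s: p = %.3g", x$test_used, x$p))
  if (!is.null(x$cohens_d)) cat(sprintf(", Cohen's d = %.3f", x$cohens_d))
  if (!is.null(x$cramers_v)) cat(sprintf(", Cramer's V = %.3f", x$cramers_v))
  cat("\n")
  invisible(x)
}

#' Approximate power for a continuous predictor in logistic regression
#'
#' Hsieh-style normal approximation for the two-sided Wald (Z) test of a
#' normally distributed predictor: with per-SD effect
#' \eqn{\beta^* = \log(OR) \cdot SD} and event rate \eqn{p} at the predictor
#' mean, \deqn{power = \Phi(|\beta^*|\sqrt{n p (1-p)} - z_{1-\alpha/2}) +
#' \Phi(-|\beta^*|\sqrt{n p (1-p)} - z_{1-\alpha/2}).}
#' At OR = 1 this returns \eqn{\alpha} (the two-sided size).
#'
#' @param or_per_unit odds ratio per unit of the predictor (> 0).
#' @param predictor_sd standard deviation of the predictor.
#' @param prevalence event rate in (0, 1).
#' @param n sample size (>= 10).
#' @param alpha two-sided significance level.
#' @return power in [0, 1].
#' @export
logistic_power <- function(or_per_unit, predictor_sd, prevalence, n,
                           alpha = 0.05) {
  if (or_per_unit <= 0) stop("or_per_unit must be > 0")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (n < 10) stop("n must be >= 10")
  b <- abs(log(or_per_unit)) * predictor_sd
  z <- qnorm(1 - alpha / 2)
  s <- sqrt(n * prevalence * (1 - prevalence))
  pnorm(b * s - z) + pnorm(-b * s - z)
}
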