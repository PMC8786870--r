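# Regression layer: fit diagnostics, per-SNP scan with BH correction,
# quartile contrasts, interaction geometry, group comparisons and power.

test_that("intercept-only logistic fit recovers the closed-form logit", {
  d <- data.frame(depression = rep(c(1, 0), c(50, 950)))
  f <- fit_glm(d, depression ~ 1, family = "logistic")
  expect_equal(f$coefficients$estimate[1], qlogis(0.05), tolerance = 1e-6)
  expect_equal(f$d_squared, 0)
})

test_that("perfect separation is flagged, not silently reported", {
  d <- data.frame(depression = rep(c(0, 1), each = 10),
                  grs = c(1:10, 21:30), sex = 0, age = 50,
                  province = factor("a"))
  f <- fit_glm(d, depression ~ grs, family = "logistic")
  expect_true(f$separation)
})

test_that("D-squared never decreases along the nested model ladder", {
  dat <- small_analysis_data()
  d2 <- vapply(1:5, function(m)
    fit_glm(dat, model_formula(m), "logistic")$d_squared, numeric(1))
  expect_true(all(d2 >= 0 & d2 <= 1))
  expect_true(d2[2] >= d2[1] && d2[3] >= d2[1])   # 1 in 2, 1 in 3
  expect_true(d2[4] >= d2[2] && d2[4] >= d2[3])   # 2,3 in 4
  expect_true(d2[5] >= d2[4])                     # 4 in 5
})

test_that("BH adjustment matches the hand step-up rule and the oracle", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p))
  }
})

test_that("the SNP scan adjusts for covariates and skips monomorphic SNPs", {
  sim <- simulate_study(n_subjects = 400, seed = 14)
  geno <- cbind(sim$genotypes, mono = 0L)
  scan <- univariate_snp_scan(geno, sim$pheno)
  expect_true(scan$skipped[scan$snp_id == "mono"])
  expect_equal(scan$reason[scan$snp_id == "mono"], "monomorphic")
  ok <- !scan$skipped
  expect_equal(scan$p_adj[ok], p.adjust(scan$p[ok], "BH"))
  one <- univariate_snp_scan(sim$genotypes[, 1, drop = FALSE], sim$pheno)
  expect_equal(one$p_adj, one$p)   # m = 1: adjusted equals raw
})

test_that("scan on BMI runs the linear branch with the normality gate", {
  sim <- simulate_study(n_subjects = 400, seed = 15)
  scan <- univariate_snp_scan(sim$genotypes[, 1:5], sim$pheno,
                              outcome = "bmi")
  expect_true(all(is.na(scan$or)))
  expect_true(attr(scan, "transform_applied") %in% c("none", "int", "log"))
  expect_true(all(is.finite(scan$beta)))
})

test_that("quartile contrasts report three ORs against Q1 and reject empty strata", {
  dat <- small_analysis_data(n = 1200, seed = 16)
  qc <- grs_quartile_contrasts(dat)
  expect_equal(qc$contrasts$quartile, c("Q2", "Q3", "Q4"))
  expect_true(all(qc$contrasts$ci_lo < qc$contrasts$or &
                    qc$contrasts$or < qc$contrasts$ci_hi))
  # strong positive GRS effect: top-vs-bottom exceeds Q2-vs-bottom
  expect_gt(qc$contrasts$or[3], qc$contrasts$or[1])
  dat2 <- dat
  dat2$quartile[dat2$quartile == "Q2"] <- "Q1"
  expect_error(grs_quartile_contrasts(dat2), "empty quartile")
})

test_that("shuffled GRS gives null quartile contrasts", {
  dat <- small_analysis_data(n = 1200, seed = 17)
  set.seed(1)
  dat$grs <- sample(dat$grs)
  dat$quartile <- assign_quartiles(dat$grs)
  qc <- grs_quartile_contrasts(dat)
  expect_true(all(qc$contrasts$ci_lo < 1 & qc$contrasts$ci_hi > 1))
})

test_that("no-interaction truth yields parallel logit-scale profiles", {
  sim <- simulate_study(n_subjects = 1650, seed = 18,
                        truth = effect_model(or_interaction = 1))
  g <- orient_to_risk(sim$genotypes, sim$annotation)
  dat <- merge(sim$pheno, compute_grs(g), by = "subject_id")
  im <- interaction_model(dat)
  # estimated interaction is compatible with zero
  expect_lt(abs(im$interaction$estimate), 3 * im$interaction$se)
  # and the marginal model's profiles are exactly parallel on the logit scale
  f4 <- fit_glm(dat, model_formula(4), "logistic")
  nd <- expand.grid(grs = c(10, 20, 30),
                    bmi = mean(dat$bmi) + c(-4, 0, 4))
  nd$sex <- mean(dat$sex); nd$age <- mean(dat$age)
  nd$province <- factor(levels(dat$province)[1],
                        levels = levels(dat$province))
  lp <- matrix(predict(f4$glm, newdata = nd, type = "link"), nrow = 3)
  expect_equal(lp[, 1] - lp[, 2], lp[, 2] - lp[, 3])
})

test_that("positive interaction steepens the risk profile with BMI", {
  sim <- simulate_study(seed = 19)
  g <- orient_to_risk(sim$genotypes, sim$annotation)
  dat <- merge(sim$pheno, compute_grs(g), by = "subject_id")
  im <- interaction_model(dat)
  expect_gt(im$interaction$estimate, 0)
  grid <- im$grid
  slopes <- vapply(split(grid, grid$bmi_stratum), function(gg)
    unname(coef(lm(qlogis(predicted_probability) ~ grs, data = gg))[2]),
    numeric(1))
  # strata are labelled "-2 SD" ... "+2 SD"; order by BMI value
  ord <- order(vapply(split(grid$bmi, grid$bmi_stratum), unique, numeric(1)))
  expect_true(all(diff(slopes[ord]) > 0))
})

test_that("group comparison reproduces the pooled-SD effect size", {
  expect_equal(round(cohens_d_pooled(22.38, 2.91, 104,
                                     20.71, 2.94, 1546), 2), 0.57)
  x <- c(rnorm(30), rnorm(30))
  r <- group_compare(c(x[1:30], x[1:30]), rep(c("a", "b"), each = 30))
  expect_equal(r$cohens_d, 0)
  # antisymmetry under swapping groups
  set.seed(6)
  v <- rnorm(80); gr <- rep(c("a", "b"), 40)
  d1 <- group_compare(v, gr)$cohens_d
  d2 <- group_compare(v, factor(gr, levels = c("b", "a")))$cohens_d
  expect_equal(d1, -d2)
})

test_that("Cramer's V hits 1 for a diagonal table, invariant to permutation", {
  m <- matrix(c(10, 0, 0, 10), 2)
  r <- group_compare(m)
  expect_equal(r$cramers_v, 1)
  set.seed(7)
  t1 <- matrix(rpois(6, 20) + 1, 2, 3)
  v1 <- group_compare(t1)$cramers_v
  v2 <- group_compare(t1[2:1, c(2, 3, 1)])$cramers_v
  expect_equal(v1, v2)
})

test_that("logistic power behaves like a two-sided Wald test", {
  expect_equal(logistic_power(1, 3, 0.06, 1650), 0.05, tolerance = 1e-10)
  # nondecreasing in n and |log OR|
  ns <- seq(100, 3000, by = 100)
  pw_n <- vapply(ns, function(n) logistic_power(1.2, 3, 0.06, n), numeric(1))
  expect_true(all(diff(pw_n) >= 0))
  ors <- seq(1.05, 2, by = 0.05)
  pw_or <- vapply(ors, function(o) logistic_power(o, 3, 0.06, 500), numeric(1))
  expect_true(all(diff(pw_or) >= 0))
  expect_equal(logistic_power(1.5, 3, 0.06, 500),
               logistic_power(1 / 1.5, 3, 0.06, 500))
  expect_error(logistic_power(0, 3, 0.06, 500), "or_per_unit")
})
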