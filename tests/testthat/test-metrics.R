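# Discrimination and reclassification metrics against hand counts and the
# Mann-Whitney / slope-difference oracles.

test_that("AUC matches hand-counted concordant pairs", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "at least one")
})

test_that("AUC equals the Mann-Whitney statistic on random instances", {
  set.seed(8)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.3))
    sc <- round(runif(n), sample(1:3, 1))   # induce ties
    expect_equal(roc_auc(sc, lab)$auc, auc_u_oracle(sc, lab))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  lab <- rbinom(100, 1, 0.3); lab[1:2] <- c(0, 1)
  sc <- rnorm(100)
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(exp(sc), lab)$auc, a)
  expect_equal(roc_auc(qlogis(plogis(sc) * 0.5 + 0.2), lab)$auc, a)
})

test_that("DeLong comparison is exact-null for identical scores and detects signal", {
  set.seed(10)
  lab <- rbinom(400, 1, 0.25); lab[1:2] <- c(0, 1)
  sc <- runif(400)
  r <- compare_auc(sc, sc, lab)
  expect_equal(r$delta, 0)
  expect_equal(r$p, 1)
  strong <- plogis(qlogis(sc) + 3 * lab)
  expect_lt(compare_auc(sc, strong, lab)$p, 0.01)
  expect_error(compare_auc(sc[-1], sc, lab), "paired")
})

test_that("IDI matches hand means and is antisymmetric in the labels", {
  lab <- c(1, 1, 0, 0)
  po <- c(0.2, 0.4, 0.1, 0.3); pn <- c(0.3, 0.5, 0.05, 0.25)
  expect_equal(idi(lab, po, pn)$est, 0.15)
  expect_equal(idi(lab, po, po)$est, 0)
  expect_equal(idi(1 - lab, po, pn)$est, -idi(lab, po, pn)$est)
})

test_that("IDI equals the difference in discrimination slopes", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(10:100, 1)
    lab <- c(1, 1, 0, 0, rbinom(n - 4, 1, 0.4))
    po <- runif(n); pn <- runif(n)
    slope <- function(p) mean(p[lab == 1]) - mean(p[lab == 0])
    expect_equal(idi(lab, po, pn)$est, slope(pn) - slope(po))
  }
})

test_that("categorical NRI follows the low/medium/high movement rules", {
  # one case up, one control down: both components 1
  expect_equal(categorical_nri(c(1, 0), c(0.20, 0.06), c(0.30, 0.04))$est, 2)
  # boundary convention: 0.05 belongs to medium, 0.25 to high
  expect_equal(categorical_nri(c(1, 0), c(0.04, 0.10), c(0.05, 0.12))$est, 1)
  expect_equal(categorical_nri(c(1, 0), c(0.20, 0.10), c(0.25, 0.12))$est, 1)
  # nobody moves
  r0 <- categorical_nri(c(1, 0, 1, 0), rep(0.1, 4), rep(0.12, 4))
  expect_equal(r0$est, 0)
  expect_true(is.na(r0$p))
  # worst case: case down, control up
  expect_equal(categorical_nri(c(1, 0), c(0.30, 0.04), c(0.20, 0.06))$est, -2)
  expect_error(categorical_nri(c(1, 0), c(0.1, 0.1), c(0.1, 0.1),
                               cuts = c(0.3, 0.2)), "increasing")
})

test_that("category-free NRI counts any directional change", {
  expect_equal(category_free_nri(c(1, 0), c(0.2, 0.1), c(0.2, 0.1))$est, 0)
  expect_equal(category_free_nri(c(1, 1, 0), c(0.2, 0.3, 0.1),
                                 c(0.25, 0.25, 0.2))$est, -1)
  expect_equal(category_free_nri(c(1, 1, 0, 0), c(0.2, 0.3, 0.2, 0.3),
                                 c(0.3, 0.4, 0.1, 0.2))$est, 2)
})

test_that("categorical NRI with saturating cuts equals the category-free NRI", {
  set.seed(12)
  cuts <- seq(0.005, 0.995, by = 0.01)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    lab <- c(1, 0, rbinom(n - 2, 1, 0.3))
    po <- round(runif(n, 0.02, 0.98), 2)   # every value sits in its own bin
    pn <- round(runif(n, 0.02, 0.98), 2)
    expect_equal(categorical_nri(lab, po, pn, cuts = cuts)$est,
                 category_free_nri(lab, po, pn)$est)
  }
})

test_that("bootstrap CIs bracket the point estimate", {
  set.seed(13)
  lab <- rbinom(300, 1, 0.2); lab[1:4] <- c(1, 1, 0, 0)
  po <- plogis(rnorm(300, -2)); pn <- plogis(qlogis(po) + 0.5 * lab + rnorm(300, 0, 0.2))
  r <- idi(lab, po, pn, boot = TRUE, B = 200, seed = 3)
  expect_true(r$ci[1] <= r$est && r$est <= r$ci[2])
  r2 <- category_free_nri(lab, po, pn, boot = TRUE, B = 200, seed = 3)
  expect_true(r2$ci[1] <= r2$est && r2$est <= r2$ci[2])
})
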