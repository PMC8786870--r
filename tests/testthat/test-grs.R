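# GRS construction: concordance screen, allele orientation, complete-case
# scoring and quartile assignment.

test_that("concordance compares fitted sign with literature direction", {
  res <- data.frame(snp_id = c("a", "b", "c", "d"),
                    beta = c(0.2, -0.2, -0.1, 0), p = c(0.5, 0.5, 0.5, 0.5))
  ann <- data.frame(snp_id = c("a", "b", "c", "d"),
                    literature_direction = c(1, 1, -1, 1))
  cc <- concordance_select(res, ann)
  expect_equal(cc$concordant, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(concordance_select(
    data.frame(snp_id = "zz", beta = 1), ann), "zz")
})

test_that("significance is not required for concordant selection", {
  res <- data.frame(snp_id = "a", beta = 0.01, p = 0.97)
  ann <- data.frame(snp_id = "a", literature_direction = 1)
  expect_true(concordance_select(res, ann)$concordant)
})

test_that("orientation flips protective SNPs and preserves missingness", {
  g <- matrix(c(0L, 1L, 2L, NA, 2L, 0L, 1L, NA), ncol = 2,
              dimnames = list(paste0("s", 1:4), c("risk", "prot")))
  ann <- data.frame(snp_id = c("risk", "prot"),
                    literature_direction = c(1, -1))
  r <- orient_to_risk(g, ann)
  expect_equal(r[, "risk"], g[, "risk"])
  expect_equal(unname(r[, "prot"]), c(0L, 2L, 1L, NA))
  g[1, 1] <- 3L
  expect_error(orient_to_risk(g, ann), "0, 1, 2")
})

test_that("GRS is the oriented allele sum with the complete-case rule", {
  r <- rbind(S1 = c(2, 1, 0, 2), S2 = rep(0, 4), S3 = rep(2, 4),
             S4 = c(1, NA, 1, 1))
  colnames(r) <- paste0("snp", 1:4)
  grs <- compute_grs(r)
  expect_equal(grs$grs, c(5L, 0L, 8L))
  expect_equal(attr(grs, "n_dropped"), 1)
  expect_equal(attr(grs, "dropped_subjects"), "S4")
  expect_error(compute_grs(r, character(0)), "empty SNP set")
})

test_that("quartile assignment uses sample quartiles, ties to the lower", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  expect_warning(qq <- assign_quartiles(rep(5, 10)), "tied")
  expect_true(all(qq == "Q1"))
  set.seed(4)
  x <- rnorm(4000)   # no ties: groups within 1 of n/4
  tab <- table(assign_quartiles(x))
  expect_true(all(abs(tab - 1000) <= 1))
  expect_error(assign_quartiles(1:3), "at least 4")
})

test_that("GRS is invariant under consistent allele relabeling", {
  sim <- simulate_study(n_subjects = 300, seed = 10,
                        panel = snp_panel_spec(6, maf = rep(0.3, 6),
                                               literature_direction = c(1, 1, 1, -1, -1, 1)))
  ann <- sim$annotation
  g1 <- compute_grs(orient_to_risk(sim$genotypes, ann))
  # relabel SNP 2: swap effect/other allele => dosage 2-g, flip direction
  geno2 <- sim$genotypes
  geno2[, 2] <- 2L - geno2[, 2]
  ann2 <- ann
  ann2$literature_direction[2] <- -ann2$literature_direction[2]
  g2 <- compute_grs(orient_to_risk(geno2, ann2))
  expect_equal(g1$grs, g2$grs)
})

test_that("total GRS equals the column-wise oriented allele total", {
  sim <- simulate_study(n_subjects = 400, seed = 11)
  r <- orient_to_risk(sim$genotypes, sim$annotation)
  grs <- compute_grs(r)
  expect_equal(sum(grs$grs), sum(colSums(r)))
})

test_that("cases carry higher mean GRS when every true effect is positive", {
  sim <- simulate_study(seed = 12)
  r <- orient_to_risk(sim$genotypes, sim$annotation)
  grs <- compute_grs(r)
  dat <- merge(sim$pheno, grs, by = "subject_id")
  expect_gt(mean(dat$grs[dat$depression == 1]),
            mean(dat$grs[dat$depression == 0]))
})
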