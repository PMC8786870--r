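# Marker QC: call rate, MAF, the Hardy-Weinberg exact test, LD R^2 and the
# full filter cascade.

test_that("call rate is the non-missing fraction, boundary retained", {
  expect_equal(call_rate(rep(1, 10)), 1.0)
  expect_equal(call_rate(c(rep(0, 19), NA)), 0.95)
  expect_equal(call_rate(c(rep(0, 18), NA, NA)), 0.90)
  expect_error(call_rate(numeric(0)), "empty")
})

test_that("minor allele frequency is computed on non-missing dosages", {
  expect_equal(minor_allele_freq(c(0, 0, 1, 2)), 0.375)
  expect_equal(minor_allele_freq(rep(0, 5)), 0)
  expect_equal(minor_allele_freq(c(1, 1)), 0.5)
  expect_equal(minor_allele_freq(c(0, NA, 1, 2, NA)), 0.375 * 4 / 3)
  expect_error(minor_allele_freq(c(NA, NA)), "missing")
})

test_that("HWE exact test matches hand-enumerated cases", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  # two het counts possible {0, 2} with probabilities {1/3, 2/3}
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_error(hwe_exact_test(-1, 0, 1), ">= 0")
  expect_error(hwe_exact_test(0, 0, 0), ">= 1")
})

test_that("HWE exact test equals the enumeration oracle on random triples", {
  set.seed(1)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    cnt <- as.vector(stats::rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
})

test_that("HWE exact test is invariant under allele relabeling", {
  set.seed(2)
  for (i in 1:50) {
    cnt <- sample(0:30, 3, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_exact_test(cnt[3], cnt[2], cnt[1]))
  }
})

test_that("LD R^2 is symmetric in reflection and near zero for independence", {
  g <- c(0, 1, 2, 1, 0, 2, 1, 1)
  expect_equal(ld_r2(g, g), 1.0)
  expect_equal(ld_r2(g, 2 - g), 1.0)
  set.seed(3)
  a <- rbinom(1e4, 2, 0.3); b <- rbinom(1e4, 2, 0.3)
  expect_lt(ld_r2(a, b), 0.01)
  expect_warning(r <- ld_r2(rep(1, 5), c(0, 1, 2, 1, 0)), "constant")
  expect_true(is.na(r))
})

test_that("run_qc applies the filter cascade with a reconciling audit trail", {
  sim <- simulate_study(n_subjects = 500, seed = 5)
  qc <- run_qc(sim$genotypes, sim$pheno,
               qc_config(hwe_alpha = 1e-6))   # keep clean panel intact
  expect_equal(ncol(qc$genotypes), 30)
  expect_equal(nrow(qc$pheno), 500)
  expect_true(all(qc$snp_qc$pass))
  # counts reconcile: input = output + dropped at each axis
  expect_equal(unname(qc$counts["snps_in"]),
               unname(qc$counts["snps_out"]) + sum(!qc$snp_qc$pass))
  expect_equal(unname(qc$counts["subjects_in"]),
               unname(qc$counts["subjects_out"]) + length(qc$subjects_dropped))
  expect_true(all(qc$snp_qc$reason[!qc$snp_qc$pass] != ""))
})

test_that("a duplicated SNP column loses exactly one member at LD pruning", {
  sim <- simulate_study(n_subjects = 400, seed = 6)
  geno <- cbind(sim$genotypes, dup = sim$genotypes[, 1])
  qc <- run_qc(geno, sim$pheno, qc_config(hwe_alpha = 1e-6))
  pair <- qc$snp_qc[qc$snp_qc$snp_id %in% c("snp_001", "dup"), ]
  expect_equal(sum(pair$ld_pruned), 1)
  # equal call rates: tie-break drops the later column
  expect_true(pair$ld_pruned[pair$snp_id == "dup"])
})

test_that("underweight subjects are excluded before genotype QC", {
  sim <- simulate_study(n_subjects = 800, underweight_rate = 0.02, seed = 7)
  n_uw <- sum(sim$pheno$bmi <= 18.5)
  expect_gt(n_uw, 0)
  qc <- run_qc(sim$genotypes, sim$pheno, qc_config(hwe_alpha = 1e-6))
  expect_equal(nrow(qc$pheno), 800 - n_uw)
  expect_equal(length(qc$subjects_dropped), n_uw)
})

test_that("run_qc is idempotent", {
  sim <- simulate_study(n_subjects = 500, seed = 8)
  q1 <- run_qc(sim$genotypes, sim$pheno, qc_config())
  q2 <- run_qc(q1$genotypes, q1$pheno, qc_config())
  expect_identical(q2$genotypes, q1$genotypes)
  expect_identical(q2$pheno, q1$pheno)
})

test_that("HWE failures can be flagged without exclusion", {
  # force a gross HWE violation in a dedicated column
  sim <- simulate_study(n_subjects = 500, seed = 9)
  bad <- rep(c(0L, 2L), length.out = 500)  # no heterozygotes at MAF 0.5
  geno <- cbind(sim$genotypes, bad = bad)
  qc_drop <- run_qc(geno, sim$pheno, qc_config())
  expect_false("bad" %in% colnames(qc_drop$genotypes))
  qc_flag <- run_qc(geno, sim$pheno, qc_config(drop_hwe_failures = FALSE))
  expect_true("bad" %in% colnames(qc_flag$genotypes))
  expect_true(qc_flag$snp_qc$hwe_fail[qc_flag$snp_qc$snp_id == "bad"])
})
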