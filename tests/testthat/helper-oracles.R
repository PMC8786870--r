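# Independent oracles used across the suite.

# Hardy-Weinberg exact p by direct enumeration of all admissible
# heterozygote counts, with multinomial conditional probabilities computed
# from log-factorials (independent of the recurrence used by the package).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_aa + n_Aa                   # one allele's count
  na <- min(na, 2 * n - na)               # minor allele
  if (na == 0) return(1)
  hets <- seq.int(na %% 2, na, by = 2)
  lp <- vapply(hets, function(h) {
    hom_a <- (na - h) / 2
    hom_A <- n - h - hom_a
    lfactorial(n) - lfactorial(hom_A) - lfactorial(h) - lfactorial(hom_a) +
      h * log(2) +
      lfactorial(na) + lfactorial(2 * n - na) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# AUC as the Mann-Whitney U statistic over n1*n0 (pairwise count, ties 1/2)
auc_u_oracle <- function(scores, labels) {
  ca <- scores[labels == 1]; co <- scores[labels == 0]
  u <- sum(vapply(ca, function(s) sum(s > co) + 0.5 * sum(s == co),
                  numeric(1)))
  u / (length(ca) * length(co))
}

# Benjamini-Hochberg step-up by direct application of the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(1, running)
  }
  adj
}

# small deterministic analysis table for model-level unit tests
small_analysis_data <- function(n = 600, seed = 42) {
  sim <- simulate_study(n_subjects = n, seed = seed)
  g <- orient_to_risk(sim$genotypes, sim$annotation)
  grs <- compute_grs(g)
  dat <- merge(sim$pheno, grs, by = "subject_id")
  dat$quartile <- assign_quartiles(dat$grs)
  dat
}
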