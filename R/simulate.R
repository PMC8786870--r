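# Synthetic cohort generator: genotypes under HWE with optional LD blocks,
# covariates of a multicentre primary-care sample, and a logistic outcome
# with a GRS-by-BMI interaction.

#' Specify a SNP panel for simulation
#'
#' Describes the marker panel the genotype simulator draws from: minor-allele
#' frequencies, optional LD blocks, a per-genotype missingness rate, the
#' literature effect direction of each SNP's minor allele, and the fraction of
#' SNPs whose simulated effect sign contradicts the literature (used to
#' exercise concordance-based selection).
#'
#' @param n_snps number of biallelic SNPs.
#' @param maf vector of minor-allele frequencies in (0, 0.5]; recycled to
#'   \code{n_snps}. The default \code{NULL} draws them from Uniform(0.05, 0.35)
#'   at simulation time, which at 30 SNPs gives a risk-score standard
#'   deviation close to 3 alleles.
#' @param ld_blocks optional list of \code{list(size =, r =)} blocks: the first
#'   \code{size} still-unassigned SNPs are coupled through a Gaussian copula
#'   calibrated so the pairwise genotype (dosage) correlation attains the
#'   target \code{r} in [0, 1). Block sizes must sum to at most \code{n_snps}.
#' @param missing_rate per-genotype missingness proportion in [0, 0.2].
#' @param literature_direction vector of +1 (minor allele reported as risk)
#'   or -1 (protective); recycled. Default all +1.
#' @param discordant_fraction fraction of SNPs whose true simulated effect
#'   sign is opposite to \code{literature_direction}.
#' @return an object of class \code{snp_panel_spec}.
#' @export
snp_panel_spec <- function(n_snps, maf = NULL, ld_blocks = NULL,
                           missing_rate = 0, literature_direction = 1L,
                           discordant_fraction = 0) {
  if (length(n_snps) != 1L || !is.finite(n_snps) || n_snps < 1)
    stop("n_snps must be a positive count")
  n_snps <- as.integer(n_snps)
  if (!is.null(maf)) {
    maf <- rep_len(as.numeric(maf), n_snps)
    bad <- which(!is.finite(maf) | maf <= 0 | maf > 0.5)
    if (length(bad))
      stop("MAF out of (0, 0.5] for SNP index ", paste(bad, collapse = ", "))
  }
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("missing_rate must be in [0, 0.2]")
  if (discordant_fraction < 0 || discordant_fraction > 1)
    stop("discordant_fraction must be in [0, 1]")
  literature_direction <- rep_len(as.integer(sign(literature_direction)), n_snps)
  if (any(literature_direction == 0L))
    stop("literature_direction entries must be +1 or -1")
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, function(b) as.integer(b$size), integer(1))
    rs <- vapply(ld_blocks, function(b) as.numeric(b$r), numeric(1))
    if (any(sizes < 2)) stop("LD block size must be >= 2")
    if (sum(sizes) > n_snps) stop("LD block sizes sum to more than n_snps")
    if (any(rs < 0 | rs >= 1)) stop("LD block target r must be in [0, 1)")
  }
  structure(list(n_snps = n_snps, maf = maf, ld_blocks = ld_blocks,
                 missing_rate = missing_rate,
                 literature_direction = literature_direction,
                 discordant_fraction = discordant_fraction),
            class = "snp_panel_spec")
}

#' Generative effect model for the simulated outcome
#'
#' Holds the true log-odds parameters of the simulated logistic outcome. The
#' linear predictor uses mean-centred covariates, so \code{intercept}
#' approximately equals \code{qlogis(prevalence)}; each SNP contributes its
#' per-allele log-odds and the interaction term multiplies the centred
#' risk-allele sum by centred BMI.
#'
#' @param prevalence target case prevalence, sets
#'   \code{intercept = qlogis(prevalence)}.
#' @param or_per_allele per-risk-allele odds ratio shared by every SNP
#'   (each \code{beta_snp} is \code{log(or_per_allele)}); the cohort this
#'   generator emulates reported 1.35 per allele.
#' @param or_interaction odds ratio per (GRS allele) x (BMI kg/m2) product
#'   unit; emulated value 1.14. Set to 1 for the no-interaction null.
#' @param beta_snp optional explicit vector of per-allele log-odds
#'   (signed relative to the minor allele after applying literature
#'   direction and discordance; see \code{\link{simulate_outcome}}).
#' @param beta_bmi,beta_sex,beta_age marginal log-odds per unit of the
#'   centred covariate; the source study reports no estimates for these,
#'   defaults are small plausible values (BMI null by default).
#' @param beta_site vector of per-site log-odds offsets (centred internally).
#' @return object of class \code{effect_model}.
#' @export
effect_model <- function(prevalence = 104 / 1650,
                         or_per_allele = 1.35,
                         or_interaction = 1.14,
                         beta_snp = NULL,
                         beta_bmi = 0,
                         beta_sex = 0.10,
                         beta_age = 0.01,
                         beta_site = NULL) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (or_per_allele <= 0 || or_interaction <= 0)
    stop("odds ratios must be positive")
  out <- structure(list(intercept = qlogis(prevalence),
                        prevalence = prevalence,
                        beta_snp = beta_snp,
                        or_per_allele = or_per_allele,
                        beta_bmi = beta_bmi, beta_sex = beta_sex,
                        beta_age = beta_age, beta_site = beta_site,
                        gamma_interaction = log(or_interaction)),
                   class = "effect_model")
  stopifnot(all(vapply(out[c("intercept", "beta_bmi", "beta_sex", "beta_age",
                             "gamma_interaction")], is.finite, logical(1))))
  out
}

# genotype dosage from a latent uniform under HWE at minor allele freq p;
# dosage counts the minor allele
.dosage_from_uniform <- function(u, p) {
  q0 <- (1 - p)^2
  q1 <- q0 + 2 * p * (1 - p)
  ifelse(u < q0, 0L, ifelse(u < q1, 1L, 2L))
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho
.bvn_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a, lower.tail = FALSE) *
                                 pnorm(b, lower.tail = FALSE))
  stats::integrate(function(z)
    stats::dnorm(z) * pnorm((rho * z - b) / sqrt(1 - rho^2)),
    a, Inf, rel.tol = 1e-10)$value
}

# genotype (dosage) correlation induced by latent correlation rho when the
# dosage is the sum of two threshold indicators of the latent normal
.genotype_cor <- function(rho, p1, p2) {
  t1 <- qnorm(c((1 - p1)^2, 1 - p1^2))
  t2 <- qnorm(c((1 - p2)^2, 1 - p2^2))
  e12 <- sum(vapply(t1, function(a)
    vapply(t2, function(b) .bvn_upper(a, b, rho), numeric(1)), numeric(2)))
  (e12 - 4 * p1 * p2) / sqrt(4 * p1 * (1 - p1) * p2 * (1 - p2))
}

# latent correlation whose thresholded genotypes attain the target dosage
# correlation (the copula attenuates, so the latent value is larger)
.latent_rho <- function(r_target, p1, p2) {
  if (r_target <= 0) return(0)
  hi <- 0.99999
  if (.genotype_cor(hi, p1, p2) < r_target) {
    warning(sprintf("target genotype correlation %.3f unattainable at MAFs %.3f/%.3f; using the maximum",
                    r_target, p1, p2))
    return(hi)
  }
  uniroot(function(r) .genotype_cor(r, p1, p2) - r_target,
          lower = r_target * 0.5, upper = hi, tol = 1e-8)$root
}

#' Simulate a genotype matrix under Hardy-Weinberg proportions
#'
#' Each SNP is drawn with genotype probabilities \eqn{(1-p)^2, 2p(1-p), p^2}
#' at its minor-allele frequency \eqn{p}. SNPs inside an LD block share a
#' latent multivariate-normal draw (Gaussian copula) with the block's target
#' pairwise correlation before thresholding into genotypes, which induces a
#' controllable genotype correlation without haplotype machinery.
#' Missingness is applied uniformly at the panel's \code{missing_rate}.
#'
#' @param panel a \code{\link{snp_panel_spec}}.
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return integer matrix subjects x SNPs with values 0/1/2/NA, column names
#'   \code{snp_001, ...}, row names \code{S00001, ...}, and the realized MAF
#'   vector in attribute \code{"maf"}.
#' @export
simulate_genotypes <- function(panel, n_subjects, seed = 1L) {
  stopifnot(inherits(panel, "snp_panel_spec"))
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  set.seed(seed)
  m <- panel$n_snps
  maf <- panel$maf
  if (is.null(maf)) maf <- runif(m, 0.05, 0.35)
  geno <- matrix(NA_integer_, n_subjects, m)
  assigned <- rep(FALSE, m)
  if (!is.null(panel$ld_blocks)) {
    for (b in panel$ld_blocks) {
      idx <- which(!assigned)[seq_len(b$size)]
      pbar <- mean(maf[idx])
      rho <- .latent_rho(b$r, pbar, pbar)
      sigma <- matrix(rho, b$size, b$size); diag(sigma) <- 1
      z <- MASS::mvrnorm(n_subjects, mu = rep(0, b$size), Sigma = sigma)
      u <- pnorm(z)
      for (k in seq_along(idx))
        geno[, idx[k]] <- .dosage_from_uniform(u[, k], maf[idx[k]])
      assigned[idx] <- TRUE
    }
  }
  for (j in which(!assigned))
    geno[, j] <- .dosage_from_uniform(runif(n_subjects), maf[j])
  if (panel$missing_rate > 0)
    geno[matrix(runif(length(geno)) < panel$missing_rate,
                n_subjects, m)] <- NA_integer_
  dimnames(geno) <- list(sprintf("S%05d", seq_len(n_subjects)),
                         sprintf("snp_%03d", seq_len(m)))
  attr(geno, "maf") <- maf
  geno
}

#' Simulate cohort covariates
#'
#' Emulates the covariate structure of a multicentre adult primary-care
#' sample: sex Bernoulli (default 62\% female), age truncated normal on
#' [18, 75], recruitment site uniform over \code{n_sites} provinces, and BMI
#' normal(27, 4) truncated at 15. By default no subject is underweight
#' (BMI <= 18.5); \code{underweight_rate} injects a fraction of underweight
#' subjects to exercise the downstream BMI exclusion filter.
#'
#' @param n_subjects subjects to draw.
#' @param n_sites number of recruitment sites (>= 1), default 7.
#' @param p_female probability of female sex (coded 1).
#' @param age_mean,age_sd mean/SD of the latent age normal before truncation.
#' @param bmi_mean,bmi_sd mean/SD of the latent BMI normal, in kg/m2.
#' @param underweight_rate fraction of subjects given BMI drawn uniformly in
#'   (15, 18.5].
#' @param seed integer seed.
#' @return data.frame with columns subject_id, sex (0/1), age, province
#'   (factor), bmi.
#' @export
simulate_covariates <- function(n_subjects, n_sites = 7, p_female = 0.62,
                                age_mean = 50, age_sd = 15,
                                bmi_mean = 27, bmi_sd = 4,
                                underweight_rate = 0, seed = 1L) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  set.seed(seed)
  sex <- rbinom(n_subjects, 1L, p_female)
  age <- .rtruncnorm(n_subjects, age_mean, age_sd, 18, 75)
  province <- factor(sample.int(n_sites, n_subjects, replace = TRUE),
                     levels = seq_len(n_sites),
                     labels = paste0("site", seq_len(n_sites)))
  bmi <- .rtruncnorm(n_subjects, bmi_mean, bmi_sd, lower = 18.5)
  bmi <- pmax(bmi, 15)
  if (underweight_rate > 0) {
    uw <- runif(n_subjects) < underweight_rate
    bmi[uw] <- runif(sum(uw), 15, 18.5)
  }
  data.frame(subject_id = sprintf("S%05d", seq_len(n_subjects)),
             sex = sex, age = age, province = province, bmi = bmi,
             stringsAsFactors = FALSE)
}

# inverse-CDF truncated normal draw
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

#' Build the SNP annotation table for a simulated panel
#'
#' One row per SNP with an identifier, synthetic chromosome/position
#' metadata, effect (minor) and other allele, the literature effect
#' direction of the minor allele (+1 risk / -1 protective), a source tag,
#' and a \code{truth_discordant} flag marking the SNPs whose simulated
#' effect sign contradicts the literature direction
#' (\code{round(discordant_fraction * n_snps)} of them, chosen from the end
#' of the panel so the assignment is deterministic).
#'
#' @param panel a \code{\link{snp_panel_spec}} with at least one SNP.
#' @return data.frame (class \code{snp_annotation}).
#' @export
make_annotation <- function(panel) {
  stopifnot(inherits(panel, "snp_panel_spec"))
  m <- panel$n_snps
  if (m < 1) stop("panel is empty")
  n_disc <- round(panel$discordant_fraction * m)
  disc <- rep(FALSE, m)
  if (n_disc > 0) disc[seq.int(m - n_disc + 1L, m)] <- TRUE
  ann <- data.frame(
    snp_id = sprintf("snp_%03d", seq_len(m)),
    chr = as.character(1L + (seq_len(m) - 1L) %% 22L),
    pos = 1000L * seq_len(m),
    effect_allele = rep_len(c("A", "C", "G", "T"), m),
    other_allele = rep_len(c("G", "T", "A", "C"), m),
    literature_direction = panel$literature_direction,
    source = rep_len(c("candidate", "gwas"), m),
    truth_discordant = disc,
    stringsAsFactors = FALSE)
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

#' Simulate the case-control outcome
#'
#' Draws depression status from a logistic model whose linear predictor uses
#' mean-centred covariates: per-SNP per-allele effects (oriented so that the
#' literature risk direction carries positive log-odds, except for SNPs
#' flagged discordant in the annotation, whose true effect sign is flipped),
#' marginal sex/age/BMI/site effects, and a
#' \code{gamma_interaction * (GRS - E[GRS]) * (BMI - mean BMI)} term, where
#' the GRS is the risk-oriented allele sum over all panel SNPs (missing
#' dosages imputed at their SNP mean for the generative sum only).
#'
#' With \code{calibrate_intercept = TRUE} the intercept is solved numerically
#' so the expected case fraction equals \code{truth$prevalence} under the
#' realized covariates; otherwise the stored \code{qlogis(prevalence)}
#' intercept is used (exact when all effects are zero).
#'
#' @param genotypes matrix from \code{\link{simulate_genotypes}}.
#' @param covariates data.frame from \code{\link{simulate_covariates}}.
#' @param truth an \code{\link{effect_model}}.
#' @param annotation matching \code{\link{make_annotation}} table.
#' @param seed integer seed.
#' @param calibrate_intercept logical, see Details.
#' @return \code{covariates} with a \code{depression} column (0/1) appended;
#'   attributes \code{"intercept_used"} and \code{"expected_prevalence"}.
#' @export
simulate_outcome <- function(genotypes, covariates, truth, annotation,
                             seed = 1L, calibrate_intercept = FALSE) {
  stopifnot(inherits(truth, "effect_model"))
  if (!identical(rownames(genotypes), covariates$subject_id))
    stop("subject sets of genotypes and covariates do not match")
  if (nrow(annotation) != ncol(genotypes))
    stop("annotation does not match genotype columns")
  m <- ncol(genotypes)
  beta <- truth$beta_snp
  if (is.null(beta)) beta <- rep(log(truth$or_per_allele), m)
  beta <- rep_len(beta, m)
  # true per-minor-allele sign: literature direction, flipped when discordant
  sgn <- annotation$literature_direction * ifelse(annotation$truth_discordant, -1, 1)

  # risk-oriented dosage (relative to literature direction) for the
  # generative GRS; mean-impute missing so the sum is defined for everyone
  g <- genotypes
  flip <- annotation$literature_direction < 0
  g[, flip] <- 2L - g[, flip]
  gm <- apply(g, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  grs_true <- rowSums(gm)

  # per-SNP effects act on the minor-allele dosage with the true sign;
  # centred at the realized mean
  dos <- apply(genotypes, 2, function(x) { x[is.na(x)] <- mean(x, na.rm = TRUE); x })
  dos_c <- sweep(dos, 2, colMeans(dos))
  eta_snp <- drop(dos_c %*% (beta * sgn))

  bmi_c <- covariates$bmi - mean(covariates$bmi)
  age_c <- covariates$age - mean(covariates$age)
  sex_c <- covariates$sex - mean(covariates$sex)
  n_sites <- nlevels(covariates$province)
  bsite <- truth$beta_site
  if (is.null(bsite)) {
    bsite <- if (n_sites > 1) seq(-0.2, 0.2, length.out = n_sites) else 0
  }
  bsite <- rep_len(bsite, n_sites)
  bsite <- bsite - mean(bsite)
  eta <- eta_snp +
    truth$beta_bmi * bmi_c + truth$beta_sex * sex_c + truth$beta_age * age_c +
    bsite[as.integer(covariates$province)] +
    truth$gamma_interaction * (grs_true - mean(grs_true)) * bmi_c

  b0 <- truth$intercept
  if (calibrate_intercept) {
    f <- function(b) mean(plogis(b + eta)) - truth$prevalence
    b0 <- uniroot(f, lower = -30, upper = 30)$root
  }
  set.seed(seed)
  p <- plogis(b0 + eta)
  out <- covariates
  out$depression <- rbinom(length(p), 1L, p)
  attr(out, "intercept_used") <- b0
  attr(out, "expected_prevalence") <- mean(p)
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper tying together \code{\link{simulate_genotypes}},
#' \code{\link{simulate_covariates}}, \code{\link{make_annotation}} and
#' \code{\link{simulate_outcome}}. Defaults emulate the cohort structure this
#' package targets: 1650 subjects over 7 sites, a 30-SNP risk panel with
#' MAF >= 0.05, ~6.3\% case prevalence, per-allele odds ratio 1.35 and
#' GRS-by-BMI interaction odds ratio 1.14 (intercept calibrated so the
#' expected case count is ~104).
#'
#' @param n_subjects,n_sites cohort dimensions.
#' @param panel a \code{\link{snp_panel_spec}}; default 30 SNPs, no missing
#'   data, all literature directions +1, no discordance.
#' @param truth an \code{\link{effect_model}}; see its defaults.
#' @param underweight_rate passed to \code{\link{simulate_covariates}}.
#' @param calibrate_intercept see \code{\link{simulate_outcome}}; default TRUE.
#' @param seed master seed; sub-stage seeds are derived from it.
#' @return list of class \code{simulated_study} with elements
#'   \code{genotypes}, \code{pheno}, \code{annotation}, \code{truth},
#'   \code{seed}.
#' @export
simulate_study <- function(n_subjects = 1650, n_sites = 7,
                           panel = snp_panel_spec(30),
                           truth = effect_model(),
                           underweight_rate = 0,
                           calibrate_intercept = TRUE,
                           seed = 1L) {
  seed <- as.integer(seed) %% 1000003L
  geno <- simulate_genotypes(panel, n_subjects, seed = seed)
  cov <- simulate_covariates(n_subjects, n_sites = n_sites,
                             underweight_rate = underweight_rate,
                             seed = seed + 1L)
  ann <- make_annotation(panel)
  pheno <- simulate_outcome(geno, cov, truth, ann, seed = seed + 2L,
                            calibrate_intercept = calibrate_intercept)
  structure(list(genotypes = geno, pheno = pheno, annotation = ann,
                 truth = truth, seed = seed),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated case-control study\n")
  cat(sprintf("  subjects: %d   SNPs: %d   cases: %d (%.1f%%)\n",
              nrow(x$pheno), ncol(x$genotypes), sum(x$pheno$depression),
              100 * mean(x$pheno$depression)))
  cat(sprintf("  truth: per-allele OR %.3f, interaction OR %.3f\n",
              x$truth$or_per_allele, exp(x$truth$gamma_interaction)))
  invisible(x)
}
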