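# Sub-stream seeds are derived from the root seed by fixed offsets so that
# each block (ages, sex, genotypes, methylation, covariates) has its own
# reproducible stream: adding a SNP perturbs only the genotype block.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1L))
}

# Solve for the latent bivariate-normal correlation that yields a target
# allele (0/1 haplotype indicator) correlation r, given the two allele
# frequencies. Alleles are thresholded latent normals (allele = 1 iff
# z < qnorm(p)), so the allele correlation is
#   (P2(q1, q2; rho) - p1 p2) / sqrt(p1 (1-p1) p2 (1-p2))
# with P2 the bivariate normal CDF; monotone in rho, solved by uniroot.
latent_ld_rho <- function(r, p1, p2, tol = 1e-9) {
  if (r == 0 || p1 %in% c(0, 1) || p2 %in% c(0, 1)) return(0)
  if (abs(r) >= 1) return(sign(r))
  q1 <- stats::qnorm(p1); q2 <- stats::qnorm(p2)
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  f <- function(rho) {
    (mvtnorm::pmvnorm(upper = c(q1, q2),
                      corr = matrix(c(1, rho, rho, 1), 2))[1] - p1 * p2) / denom - r
  }
  stats::uniroot(f, c(-0.9999, 0.9999), tol = tol)$root
}

#' Simulate SNP genotypes with pairwise linkage disequilibrium
#'
#' Draws two haplotypes per subject from a latent Gaussian-copula model.
#' Each haplotype's alleles are thresholded latent normals whose latent
#' correlation is calibrated so the realized pairwise allele correlation
#' equals the requested `ld_r` entry; `|r| = 1` is reproduced exactly by
#' copying the latent variable (complete LD). The genotype is the number
#' of risk alleles carried (0/1/2).
#'
#' @param n number of subjects.
#' @param snps data.frame with `id` and `risk_allele_freq`.
#' @param ld_r symmetric allele-correlation matrix over the SNPs.
#' @param seed integer seed; output is deterministic given the seed.
#' @return Integer matrix `n` x SNPs of risk-allele counts, with SNP ids as
#'   column names.
#' @export
generate_genotypes <- function(n, snps, ld_r, seed = 1L) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  k <- nrow(snps)
  ld_r <- as.matrix(ld_r)
  check_corr_matrix(ld_r, snps$id, "ld_r", name_pair = TRUE)
  p <- snps$risk_allele_freq
  # calibrate latent correlations pairwise
  L <- diag(k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      L[i, j] <- L[j, i] <- latent_ld_rho(ld_r[i, j], p[i], p[j])
    }
  }
  ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    off <- abs(L); diag(off) <- 0
    idx <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "ld_r is not jointly attainable (latent matrix not positive semi-definite); check pair (%s, %s)",
      snps$id[idx[1]], snps$id[idx[2]]))
  }
  U <- chol(nearest_psd(L))
  set.seed(derive_seed(seed, 0))
  G <- matrix(0L, n, k, dimnames = list(NULL, snps$id))
  thr <- stats::qnorm(p)
  for (h in 1:2) {
    Z <- matrix(stats::rnorm(n * k), n, k) %*% U
    G <- G + matrix(as.integer(sweep(Z, 2, thr, `<`)), n, k)
  }
  dimnames(G) <- list(NULL, snps$id)
  G
}

# jitter-free PSD repair for matrices that are PSD up to rounding
nearest_psd <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= tol) return(M)
  v <- pmax(e$values, tol)
  R <- e$vectors %*% (v * t(e$vectors))
  D <- 1 / sqrt(diag(R))
  R * outer(D, D)
}

#' Simulate correlated percent-methylation values
#'
#' For each subject a latent vector is drawn from a zero-mean unit-variance
#' multivariate normal with the subject's group latent correlation matrix
#' (a Gaussian copula on the percent scale); the CpG value is
#' `mean + sd * z + sum_s beta[s, cpg] * (g_s - 2 * freq_s) +
#' slope[cpg] * (age - mean_age)`, clipped to \[0, 100\]. The genotype term
#' is centered at its population expectation so the configured marginal
#' mean remains the population mean for any `beta`.
#'
#' @param genotypes integer matrix of risk-allele counts (may have 0 columns).
#' @param group_labels character vector of group labels, one per subject.
#' @param ages numeric ages in years, one per subject.
#' @param config a `generator_config`.
#' @param seed integer seed.
#' @return Numeric matrix subjects x CpGs of percent methylation in
#'   \[0, 100\], CpG labels as column names.
#' @export
generate_methylation <- function(genotypes, group_labels, ages, config,
                                 seed = config$seed) {
  validate_generator_config(config)
  n <- length(group_labels)
  if (length(ages) != n) stop("ages and group_labels lengths differ")
  if (nrow(genotypes) != n)
    stop(sprintf("genotype block has %d rows but %d subjects were given",
                 nrow(genotypes), n))
  if (!identical(colnames(genotypes), config$snps$id))
    stop("genotype columns do not match the configured SNPs")
  cpgs <- config$cpgs
  labels <- vapply(config$groups, `[[`, "", "label")
  if (!all(group_labels %in% labels)) stop("unknown group label in group_labels")
  # centered genotype effect, identical for all groups (cis effect)
  gc <- sweep(genotypes, 2, 2 * config$snps$risk_allele_freq, `-`)
  eff_geno <- gc %*% config$beta                     # n x cpgs
  eff_age <- outer(ages - config$age_model$mean_age, config$age_model$slope)
  M <- matrix(NA_real_, n, length(cpgs), dimnames = list(NULL, cpgs))
  set.seed(derive_seed(seed, 1))
  for (g in config$groups) {
    idx <- which(group_labels == g$label)
    if (!length(idx)) next
    U <- chol(nearest_psd(config$latent_corr[[g$label]]))
    Z <- matrix(stats::rnorm(length(idx) * length(cpgs)),
                length(idx), length(cpgs)) %*% U
    mu <- unlist(g$mean)[cpgs]; sd <- unlist(g$sd)[cpgs]
    M[idx, ] <- sweep(sweep(Z, 2, sd, `*`), 2, mu, `+`) +
      eff_geno[idx, , drop = FALSE] + eff_age[idx, , drop = FALSE]
  }
  pmin(pmax(M, 0), 100)
}

#' Generate a complete synthetic cohort
#'
#' Assembles a full cohort table from a generator configuration: subject
#' ids, group labels, truncated-normal ages, sex, LD-structured genotypes,
#' copula-correlated methylation with additive cis-genotype and age
#' effects, and optional covariates (HbA1c, disease duration) drawn
#' independently of methylation. Identical configuration (including seed)
#' yields an identical table.
#'
#' @param config a `generator_config`, e.g. from [cohort_config()].
#' @param seed optional override of `config$seed`.
#' @return A validated cohort `data.frame` in the canonical column layout
#'   (see [read_cohort()]).
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_generator_config(config)
  groups <- config$groups
  ns <- vapply(groups, `[[`, 0, "n")
  labels <- vapply(groups, `[[`, "", "label")
  group <- rep(labels, ns)
  n <- sum(ns)
  subject_id <- unlist(lapply(seq_along(groups), function(i)
    sprintf("%s_%04d", labels[i], seq_len(ns[i]))))

  am <- config$age_model
  set.seed(derive_seed(seed, 2))
  age <- numeric(n)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    mu <- if (is.null(g$age_mean)) am$mean_age else g$age_mean
    s <- if (is.null(g$age_sd)) am$sd_age else g$age_sd
    a <- stats::rnorm(ns[i], mu, s)
    age[group == labels[i]] <- pmin(pmax(a, am$min_age), am$max_age)
  }
  age <- round(age, 1)

  set.seed(derive_seed(seed, 3))
  sex <- character(n)
  for (i in seq_along(groups)) {
    pm <- groups[[i]]$prop_male
    if (is.null(pm)) pm <- 0.5
    sex[group == labels[i]] <-
      ifelse(stats::runif(ns[i]) < pm, "M", "F")
  }

  geno <- generate_genotypes(n, config$snps, config$ld_r,
                             seed = derive_seed(seed, 4))
  # percent readouts carry ~2 decimals of precision; rounding here makes the
  # TSV serialization lossless for generated cohorts
  meth <- round(generate_methylation(geno, group, age, config,
                                     seed = derive_seed(seed, 5)), 2)

  set.seed(derive_seed(seed, 6))
  hba1c <- rep(NA_real_, n); duration <- rep(NA_real_, n)
  for (i in seq_along(groups)) {
    cov <- groups[[i]]$covariates
    if (is.null(cov)) next
    idx <- which(group == labels[i])
    if (!is.null(cov$hba1c))
      hba1c[idx] <- round(stats::rnorm(length(idx), cov$hba1c$mean, cov$hba1c$sd), 1)
    if (!is.null(cov$duration))
      duration[idx] <- round(pmax(stats::rnorm(length(idx), cov$duration$mean,
                                               cov$duration$sd), 0), 1)
  }

  tab <- data.frame(subject_id = subject_id, group = group, age = age,
                    sex = sex, stringsAsFactors = FALSE)
  meth_df <- as.data.frame(meth)
  names(meth_df) <- paste0("meth_", config$cpgs)
  geno_df <- as.data.frame(geno)
  names(geno_df) <- paste0("geno_", config$snps$id)
  tab <- cbind(tab, meth_df, geno_df,
               data.frame(hba1c = hba1c, duration = duration))
  validate_cohort(tab)
  tab
}
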