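# Independent brute-force oracles used to check the delegated statistics.

# Two-sided rank-sum p by full enumeration of all choose(n1+n2, n1)
# assignments of the pooled ranks to sample a (no ties assumed).
wilcoxon_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  all_ranks <- rank(seq_len(n1 + n2))
  ws <- apply(sets, 2, function(idx) sum(all_ranks[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(ws <= w_obs)
  p_high <- mean(ws >= w_obs)
  min(1, 2 * min(p_low, p_high))
}

# Two-sided Fisher exact p by enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities <= observed
# (with the conventional relative tolerance).
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A minimal hand-built valid cohort (n subjects per group, constant-free
# methylation, a few NAs optional).
tiny_cohort <- function(n_case = 6, n_control = 6, seed = 42) {
  set.seed(seed)
  n <- n_case + n_control
  tab <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = rep(c("T1D", "control"), c(n_case, n_control)),
    age = round(runif(n, 5, 20), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (cpg in cpg_sites()$cpg)
    tab[[paste0("meth_", cpg)]] <- round(runif(n, 40, 90), 2)
  for (s in ins_snps())
    tab[[paste0("geno_", s)]] <- sample(0:2, n, replace = TRUE)
  tab$hba1c <- NA_real_
  tab$duration <- NA_real_
  tab
}

# Single-group null config: identity copula, no genotype or age effects.
null_config <- function(n = 5000, mean = 60, sd = 5, seed = 7,
                        latent = diag(7)) {
  cpgs <- cpg_sites()$cpg
  dimnames(latent) <- list(cpgs, cpgs)
  generator_config(
    groups = list(list(label = "g", n = n,
                       mean = setNames(rep(mean, 7), cpgs),
                       sd = setNames(rep(sd, 7), cpgs))),
    latent_corr = list(g = latent),
    snps = data.frame(id = "rs689", risk_allele_freq = 0.5),
    ld_r = matrix(1, 1, 1),
    age_model = list(mean_age = 12, sd_age = 4, min_age = 1, max_age = 30),
    seed = seed)
}
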