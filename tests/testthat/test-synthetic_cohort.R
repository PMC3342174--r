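test_that("genotype generator obeys Hardy-Weinberg, degenerate and perfect-LD cases", {
  snps1 <- data.frame(id = "s1", risk_allele_freq = 1)
  g <- generate_genotypes(50, snps1, matrix(1, 1, 1), seed = 1)
  expect_true(all(g == 2L))

  snps <- data.frame(id = "s1", risk_allele_freq = 0.5)
  g <- generate_genotypes(10000, snps, matrix(1, 1, 1), seed = 2)
  props <- tabulate(g + 1L, 3) / 10000
  se <- sqrt(c(.25, .5, .25) * (1 - c(.25, .5, .25)) / 10000)
  expect_true(all(abs(props - c(.25, .5, .25)) < 3 * se))

  snps2 <- data.frame(id = c("a", "b"), risk_allele_freq = c(0.4, 0.4))
  ld <- matrix(c(1, 1, 1, 1), 2)
  g2 <- generate_genotypes(500, snps2, ld, seed = 3)
  expect_identical(g2[, "a"], g2[, "b"])
})

test_that("realized allele correlation matches the requested LD", {
  snps <- data.frame(id = c("a", "b"), risk_allele_freq = c(0.70, 0.68))
  ld <- matrix(c(1, .5, .5, 1), 2)
  set.seed(11)
  n <- 40000
  g <- generate_genotypes(n, snps, ld, seed = 11)
  # genotype correlation equals haplotype allele correlation under
  # independent haplotype draws
  r_hat <- cor(g[, 1], g[, 2])
  expect_lt(abs(r_hat - 0.5), 4 / sqrt(n) * 2)
})

test_that("jointly unattainable LD is rejected naming a pair", {
  snps <- data.frame(id = c("a", "b", "c"), risk_allele_freq = rep(0.5, 3))
  ld <- matrix(c(1, .95, -.95, .95, 1, .95, -.95, .95, 1), 3)
  expect_error(check_corr_matrix <- generate_genotypes(10, snps, ld, seed = 1),
               "not positive semi-definite|not jointly attainable")
})

test_that("marginal and copula fidelity hold under the null-effect config", {
  latent <- diag(7)
  latent[1, 4] <- latent[4, 1] <- 0.6   # m19 - m135
  cfg <- null_config(n = 5000, mean = 60, sd = 5, seed = 99, latent = latent)
  tab <- generate_cohort(cfg)
  n <- 5000
  for (cpg in cpg_sites()$cpg) {
    v <- tab[[paste0("meth_", cpg)]]
    expect_lt(abs(mean(v) - 60), 3 * 5 / sqrt(n))
    expect_lt(abs(sd(v) - 5), 4 * 5 / sqrt(n))
  }
  r <- cor(tab$meth_m19, tab$meth_m135)
  expect_lt(abs(r - 0.6), 4 / sqrt(n))
  expect_lt(abs(cor(tab$meth_m69, tab$meth_m102)), 4 / sqrt(n))
})

test_that("T1D calibration reproduces the configured case-control difference at CpG -135", {
  cfg <- cohort_config("t1d_default")
  tab <- generate_cohort(cfg, seed = 123)
  d <- mean(tab$meth_m135[tab$group == "T1D"]) -
       mean(tab$meth_m135[tab$group == "control"])
  se <- sqrt(9^2 / 485 + 5^2 / 317)
  expect_lt(abs(d - (-16)), 3 * se)
})

test_that("additive genotype effects are monotone and centered", {
  cfg <- cohort_config("t1d_default")
  cfg$groups[[1]]$n <- 4000; cfg$groups[[2]]$n <- 1000
  tab <- generate_cohort(cfg, seed = 5)
  cases <- tab[tab$group == "T1D", ]
  m <- tapply(cases$meth_m180, cases$geno_rs689, mean)
  expect_true(all(diff(m[c("0", "1", "2")]) > 0))
  # centering: population mean stays at the configured marginal mean
  expect_lt(abs(mean(cases$meth_m180) - 69), 3 * 7 / sqrt(4000) + 0.2)
  # CpGs with zero beta are flat in genotype (within noise)
  m0 <- tapply(cases$meth_m135, cases$geno_rs689, mean)
  expect_lt(max(m0) - min(m0), 1.5)
})

test_that("cohorts are deterministic in the seed and structurally valid", {
  cfg <- cohort_config("t1d_default")
  a <- generate_cohort(cfg, seed = 77)
  b <- generate_cohort(cfg, seed = 77)
  expect_identical(a, b)
  c_ <- generate_cohort(cfg, seed = 78)
  expect_false(identical(a, c_))

  expect_equal(sum(a$group == "T1D"), 485)
  expect_equal(sum(a$group == "control"), 317)
  expect_false(anyDuplicated(a$subject_id) > 0)
  expect_true(all(a$age >= 1 & a$age <= 30))
  expect_true(all(a$sex %in% c("M", "F")))
  meths <- as.matrix(a[, paste0("meth_", cpg_sites()$cpg)])
  expect_true(all(meths >= 0 & meths <= 100))
  genos <- as.matrix(a[, paste0("geno_", ins_snps())])
  expect_true(all(genos %in% 0:2))
  # covariates only where configured
  expect_true(all(is.na(a$hba1c[a$group == "control"])))
  expect_true(all(!is.na(a$hba1c[a$group == "T1D"])))
})

test_that("values are clipped to [0, 100] for near-boundary marginals", {
  cfg <- null_config(n = 3000, mean = 98, sd = 5, seed = 13)
  tab <- generate_cohort(cfg)
  m <- as.matrix(tab[, paste0("meth_", cpg_sites()$cpg)])
  expect_true(all(m <= 100))
  expect_gt(max(m), 99.9)   # clipping actually engaged
})

test_that("aging preset produces a recoverable negative age trend", {
  cfg <- cohort_config("aging_controls")
  cfg$groups[[1]]$n <- 2000
  tab <- generate_cohort(cfg, seed = 21)
  tr <- age_trend(tab$meth_m19, tab$age)
  expect_lt(abs(unname(tr$statistic["slope"]) - (-0.15)), 3 * tr$extra$se_slope)
  expect_equal(tr$direction, -1)
})

test_that("dimension mismatches and empty groups are rejected", {
  cfg <- cohort_config("t1d_default")
  g <- generate_genotypes(10, cfg$snps, cfg$ld_r, seed = 1)
  expect_error(generate_methylation(g, rep("T1D", 11), rep(12, 11), cfg),
               "genotype block")
  expect_error(generate_methylation(g, rep("bogus", 10), rep(12, 10), cfg),
               "unknown group")
  cfg$groups[[2]]$n <- 0
  expect_error(generate_cohort(cfg), "empty group")
})
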