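test_that("small-sample rank-sum p equals full enumeration", {
  expect_equal(wilcoxon_case_control(c(1, 2), c(3, 4))$p_value, 1 / 3)
  set.seed(101)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(100, n1 + n2)           # distinct -> no ties
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    expect_equal(wilcoxon_case_control(a, b)$p_value,
                 wilcoxon_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("rank-sum handles identity and degenerate inputs", {
  set.seed(5)
  x <- rnorm(300)
  res <- wilcoxon_case_control(x, x)
  expect_gt(res$p_value, 0.99)
  expect_warning(res2 <- wilcoxon_case_control(rep(3, 5), rep(3, 8)),
                 "identical")
  expect_equal(res2$p_value, 1)
  expect_error(wilcoxon_case_control(numeric(0), 1:3), "non-missing")
})

test_that("two-group Kruskal-Wallis equals the Wilcoxon normal approximation (H = z^2)", {
  set.seed(31)
  for (rep in 1:10) {
    v <- round(c(rnorm(25), rnorm(30, 0.3)), 1)  # coarse rounding injects ties
    g <- rep(0:1, c(25, 30))
    p_kw <- kruskal_wallis_by_genotype(v, g)$p_value
    p_w <- wilcoxon_case_control(v[g == 0], v[g == 1])$p_value
    expect_equal(p_kw, p_w, tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis degenerate inputs behave as specified", {
  expect_error(kruskal_wallis_by_genotype(1:5, rep(0, 5)), "two genotype groups")
  res <- kruskal_wallis_by_genotype(rep(4, 9), rep(0:2, 3))
  expect_equal(unname(res$statistic["H"]), 0)
  expect_equal(res$p_value, 1)
})

test_that("null Kruskal-Wallis p-values are uniform", {
  set.seed(61)
  ps <- replicate(400, {
    v <- rnorm(36)
    kruskal_wallis_by_genotype(v, rep(0:2, each = 12))$p_value
  })
  # rank tests have a discrete p distribution: ties in ps are expected
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})

test_that("correlation matrix: exact, null and recovery behavior", {
  x <- 1:50
  M <- cbind(a = x, b = 2 * x + 1, c = rnorm(50))
  cm <- correlation_matrix(M)
  expect_equal(cm$r["a", "b"], 1)
  expect_equal(diag(cm$r), c(a = 1, b = 1, c = 1))
  expect_equal(cm$r, t(cm$r))

  set.seed(71)
  Mi <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("u", "v")))
  expect_lt(abs(correlation_matrix(Mi)$r["u", "v"]), 0.1)

  # latent rho = 0.77 at n = 485 recovered within 0.05 (Fisher-z scale SE)
  cfg <- cohort_config("t1d_default")
  tab <- generate_cohort(cfg, seed = 202)
  cases <- tab[tab$group == "T1D", ]
  r <- correlation_matrix(cases[, meth_cols <- paste0("meth_", cpg_sites()$cpg)])$r
  expect_lt(abs(r["meth_m19", "meth_m135"] - 0.77), 0.05)

  # constant column flagged undefined, not silently zero
  Mc <- cbind(a = rep(1, 10), b = rnorm(10))
  expect_warning(cmc <- correlation_matrix(Mc), "undefined")
  expect_true(cmc$undefined["a", "b"])
  expect_true(is.na(cmc$r["a", "b"]))
})

test_that("age trend recovers a configured slope and rejects degenerate input", {
  set.seed(81)
  ages <- runif(2000, 5, 25)
  v <- 70 - 0.2 * ages + rnorm(2000, 0, 6)
  tr <- age_trend(v, ages)
  expect_lt(abs(unname(tr$statistic["slope"]) + 0.2), 3 * tr$extra$se_slope)
  expect_error(age_trend(c(1, 2), c(3, 4)), "at least 3")
  expect_error(age_trend(rnorm(10), rep(12, 10)), "constant")
})

test_that("age-adjusted logistic regression: null, direction, separation", {
  set.seed(91)
  n <- 4000
  y <- rep(0:1, each = n / 2)
  x <- rnorm(n, 60, 5)          # independent of disease
  ages <- runif(n, 5, 25)
  res <- logistic_adjusted(y, x, ages)
  expect_lt(abs(unname(res$statistic["log_or"])), 3 * res$extra$se)

  # configured case hypomethylation forces a protective per-percent OR
  cfg <- cohort_config("t1d_default")
  tab <- generate_cohort(cfg, seed = 303)
  res2 <- logistic_adjusted(tab$group == "T1D", tab$meth_m135, tab$age)
  expect_lt(res2$extra$or, 1)
  expect_lt(res2$p_value, 1e-10)

  # deterministic separation -> explicit error
  expect_error(
    logistic_adjusted(rep(c(1, 0), each = 20), c(rnorm(20, 10), rnorm(20, 90)),
                      runif(40, 5, 25)),
    "separation")
  expect_error(logistic_adjusted(rep(1, 10), rnorm(10), runif(10)), "both disease classes")
})

test_that("Fisher exact p matches margin enumeration and its symmetries", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_value, 1)
  set.seed(111)
  for (rep in 1:25) {
    tab <- matrix(rpois(4, 4) + 1, 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_enum_p(tab), tolerance = 1e-10)
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p_value, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p_value, p, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
  # cohort-scale table stays numerically stable
  p_big <- fisher_exact_2x2(matrix(c(70, 0, 415, 317), 2))$p_value
  expect_lt(p_big, 2e-16)
  expect_gt(p_big, 0)
})

test_that("reported p-values stay within (0, 1]", {
  set.seed(121)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(9, 2 * rep)
    p <- wilcoxon_case_control(a, b)$p_value
    expect_gt(p, 0); expect_lte(p, 1)
    pk <- kruskal_wallis_by_genotype(c(a, b), rep(0:1, c(8, 9)))$p_value
    expect_gt(pk, 0); expect_lte(pk, 1)
  }
})
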