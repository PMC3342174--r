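make_ref_cohort <- function(values_by_cpg, group = "control") {
  n <- length(values_by_cpg[[1]])
  tab <- data.frame(subject_id = sprintf("%s%03d", group, seq_len(n)),
                    group = group, age = 12, sex = "F",
                    stringsAsFactors = FALSE)
  for (cpg in cpg_sites()$cpg)
    tab[[paste0("meth_", cpg)]] <-
      if (cpg %in% names(values_by_cpg)) values_by_cpg[[cpg]] else rep(60 + seq_len(n), length.out = n)
  tab
}

test_that("reference fit computes per-CpG mean and sample SD (n-1)", {
  tab <- make_ref_cohort(list(m19 = c(60, 64, 68)))
  ref <- fit_reference(tab)
  expect_equal(ref$mean[ref$cpg == "m19"], 64)
  expect_equal(ref$sd[ref$cpg == "m19"], 4)
  expect_equal(ref$n[ref$cpg == "m19"], 3L)
  # refit on the same data is idempotent
  expect_equal(fit_reference(tab), ref)
})

test_that("degenerate references are rejected", {
  tab <- make_ref_cohort(list(m19 = c(64, 64, 64)))
  expect_error(fit_reference(tab), "zero variance")
  tab2 <- make_ref_cohort(list(m19 = c(60, NA, NA, 64)))
  expect_error(fit_reference(tab2), "usable control values")
  expect_error(fit_reference(tab2[0, ]), "empty")
})

test_that("the -2SD threshold is mean minus twice the SD", {
  tab <- make_ref_cohort(list(m19 = c(58, 64, 70)))
  ref <- fit_reference(tab)
  ref$mean[ref$cpg == "m19"] <- 64; ref$sd[ref$cpg == "m19"] <- 6
  expect_equal(unname(hypomethylation_threshold(ref, "m19")), 64 - 12)
  ref$mean[ref$cpg == "m19"] <- 68; ref$sd[ref$cpg == "m19"] <- 5
  expect_equal(unname(hypomethylation_threshold(ref, "m19")), 58)
  expect_error(hypomethylation_threshold(ref, "m999"), "not in reference")
})

test_that("classification uses strict 'below' and propagates missingness", {
  ctrl <- make_ref_cohort(list(m19 = c(58, 64, 70)))   # mean 64, sd 6, thr 52
  ref <- fit_reference(ctrl)
  tab <- tiny_cohort(n_case = 3, n_control = 0, seed = 3)
  tab$meth_m19 <- c(51, 52, NA)
  flags <- classify_subjects(tab, ref)
  expect_identical(unname(flags$hypo[, "m19"]), c(TRUE, FALSE, NA))
  # monotonicity: lowering a value never un-flags
  tab2 <- tab; tab2$meth_m19 <- c(40, 51.9, 10)
  flags2 <- classify_subjects(tab2, ref)
  expect_true(all(flags2$hypo[, "m19"][!is.na(flags$hypo[, "m19"]) & flags$hypo[, "m19"]]))
  # increasing the sd never increases the flag count
  ref_wide <- ref; ref_wide$sd <- ref$sd * 2
  flags_wide <- classify_subjects(tab2, ref_wide)
  expect_lte(sum(flags_wide$hypo, na.rm = TRUE), sum(flags2$hypo, na.rm = TRUE))
})

test_that("pattern detection is a strict conjunction excluding incomplete subjects", {
  ctrl <- make_ref_cohort(list(m19 = c(58, 64, 70), m135 = c(62, 68, 74),
                               m234 = c(56, 62, 68)))
  ref <- fit_reference(ctrl)
  tab <- tiny_cohort(n_case = 4, n_control = 0, seed = 8)
  thr <- hypomethylation_threshold(ref)
  tab$meth_m19 <- thr["m19"] - c(1, 1, 1, 1)
  tab$meth_m135 <- thr["m135"] - c(1, -1, 1, 1)   # subject 2 not hypo at m135
  tab$meth_m234 <- c(thr["m234"] - 1, thr["m234"] - 1, NA, thr["m234"] - 1)
  flags <- classify_subjects(tab, ref)
  flags <- detect_pattern(flags, c("m19", "m135", "m234"))
  member <- flags$patterns$triple_hypo
  expect_identical(as.vector(member), c(TRUE, FALSE, FALSE, TRUE))
  # pattern count bounded by the per-CpG flag counts
  expect_lte(sum(member), min(colSums(flags$hypo[, c("m19", "m135", "m234")],
                                      na.rm = TRUE)))
  expect_error(detect_pattern(flags, character()), "nonempty")
  expect_error(detect_pattern(flags, "m999"), "not classified")
})

test_that("pattern percentages follow the count/n integer rounding convention", {
  counts <- attr(detect_pattern(structure(list(
    hypo = matrix(rep(c(TRUE, FALSE), c(70, 415)), ncol = 1,
                  dimnames = list(sprintf("s%03d", 1:485), "m19")),
    thresholds = c(m19 = 50), group = setNames(rep("T1D", 485), sprintf("s%03d", 1:485)),
    patterns = list()), class = "flag_matrix"), "m19")$patterns$triple_hypo, "counts")
  expect_equal(counts$members, 70L)
  expect_equal(counts$percent, 14L)
})

test_that("pattern contingency table and its degenerate cases", {
  mk_flags <- function(n, n_member, prefix, group) {
    hypo <- matrix(rep(c(TRUE, FALSE), c(n_member, n - n_member)), ncol = 1,
                   dimnames = list(sprintf("%s%04d", prefix, seq_len(n)), "m19"))
    f <- structure(list(hypo = hypo, thresholds = c(m19 = 50),
                        group = setNames(rep(group, n), rownames(hypo)),
                        patterns = list()), class = "flag_matrix")
    detect_pattern(f, "m19", name = "pat")
  }
  cases <- mk_flags(485, 70, "c", "T1D")
  controls <- mk_flags(317, 0, "k", "control")
  res <- pattern_contingency(cases, controls, "pat")
  expect_equal(unname(res$table), matrix(c(70L, 0L, 415L, 317L), 2))
  expect_lt(res$fisher$p_value, 2e-16)
  # overlapping ids rejected
  controls_dup <- mk_flags(317, 0, "c", "control")
  expect_error(pattern_contingency(cases, controls_dup, "pat"), "share subject ids")
  # zero-member column margin -> degenerate
  none_a <- mk_flags(10, 0, "a", "g1"); none_b <- mk_flags(10, 0, "b", "g2")
  expect_error(pattern_contingency(none_a, none_b, "pat"), "margin")
})

test_that("flag rate converges to Phi(-2) on independent Gaussian controls", {
  set.seed(501)
  n_ref <- 100000; n_test <- 100000
  mk <- function(n, prefix) {
    tab <- data.frame(subject_id = sprintf("%s%06d", prefix, seq_len(n)),
                      group = "control", age = 12, sex = "F",
                      stringsAsFactors = FALSE)
    for (cpg in cpg_sites()$cpg)
      tab[[paste0("meth_", cpg)]] <- rnorm(n, 60, 5)
    tab
  }
  ref <- fit_reference(mk(n_ref, "r"))
  flags <- classify_subjects(mk(n_test, "t"), ref)
  target <- pnorm(-2)
  for (cpg in cpg_sites()$cpg) {
    rate <- mean(flags$hypo[, cpg])
    expect_lt(abs(rate - target), 4 * sqrt(target * (1 - target) / n_test) + 0.001)
  }
})
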