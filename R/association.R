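# uniform container for a single inferential result
assoc_result <- function(unit, test, statistic, p_value, direction = NA_real_,
                         n = NA_integer_, group_summaries = NULL, extra = list()) {
  stopifnot(is.finite(p_value), p_value > 0, p_value <= 1)
  structure(list(unit = unit, test = test, statistic = statistic,
                 p_value = p_value, direction = direction, n = n,
                 group_summaries = group_summaries, extra = extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result %s: %s>\n", x$test, x$unit))
  cat(sprintf("  %s = %.6g, p = %s\n", names(x$statistic)[1], x$statistic[1],
              format_p(x$p_value)))
  invisible(x)
}

#' Display formatting for p-values
#'
#' Mirrors the R convention of flooring displayed p-values at
#' `< 2.2e-16`; machine-readable outputs always keep the computed value.
#'
#' @param p numeric p-value(s).
#' @return Character representation.
#' @export
format_p <- function(p) {
  ifelse(p < 2.2e-16, "<2.2e-16", formatC(p, format = "g", digits = 3))
}

group_summary <- function(values, labels) {
  do.call(rbind, lapply(split(values, labels), function(v) {
    v <- v[!is.na(v)]
    data.frame(n = length(v), mean = mean(v), sd = stats::sd(v))
  })) -> s
  s$group <- rownames(s); rownames(s) <- NULL
  s[, c("group", "n", "mean", "sd")]
}

#' Two-sample Wilcoxon rank-sum test for case-control methylation
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of percent
#' methylation between two groups. The exact null distribution is used
#' when both samples have at most 10 observations and there are no ties;
#' otherwise the normal approximation with mid-ranks and tie-corrected
#' variance is used, without continuity correction (keeping the identity
#' with the two-group Kruskal-Wallis chi-square testable).
#'
#' @param values_a,values_b numeric vectors (NAs dropped); conventionally
#'   cases first, controls second.
#' @param unit label for the tested unit (e.g. a CpG).
#' @return An `assoc_result` with statistic `W`, the two-sided p-value and
#'   `direction` = sign of (mean a - mean b).
#' @export
wilcoxon_case_control <- function(values_a, values_b, unit = "") {
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (!length(a) || !length(b)) stop("both samples need at least one non-missing value")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    warning("all values identical across both samples; p = 1")
    return(assoc_result(unit, "wilcoxon_rank_sum", c(W = length(a) * length(b) / 2),
                        1, direction = 0, n = length(pooled),
                        group_summaries = group_summary(pooled,
                          rep(c("a", "b"), c(length(a), length(b))))))
  }
  use_exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(pooled)
  wt <- stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = use_exact, correct = FALSE)
  assoc_result(unit, "wilcoxon_rank_sum", c(W = unname(wt$statistic)),
               min(wt$p.value, 1),
               direction = sign(mean(a) - mean(b)), n = length(pooled),
               group_summaries = group_summary(pooled,
                 rep(c("a", "b"), c(length(a), length(b)))),
               extra = list(exact = use_exact))
}

#' Kruskal-Wallis test of methylation across genotype groups
#'
#' Rank-based k-group comparison used for allele-specific methylation:
#' percent methylation vs risk-allele count (0/1/2). Ties are handled by
#' mid-ranks with the tie-corrected H statistic; p from the chi-square
#' distribution with k - 1 degrees of freedom. With two groups the
#' chi-square p equals the Wilcoxon normal-approximation p (H = z^2).
#'
#' @param values numeric methylation values.
#' @param genotypes group labels (risk-allele counts); pairs with missing
#'   values or genotypes are dropped.
#' @param unit label for the tested unit (e.g. "rs689 x CpG -180").
#' @return An `assoc_result` with statistic `H`, df, p and `direction` =
#'   sign of the slope of group mean on genotype.
#' @export
kruskal_wallis_by_genotype <- function(values, genotypes, unit = "") {
  keep <- !is.na(values) & !is.na(genotypes)
  v <- values[keep]; g <- genotypes[keep]
  k <- length(unique(g))
  if (k < 2) stop("at least two genotype groups with data are required")
  if (length(unique(v)) == 1) {
    return(assoc_result(unit, "kruskal_wallis", c(H = 0), 1, direction = 0,
                        n = length(v), group_summaries = group_summary(v, g),
                        extra = list(df = k - 1)))
  }
  kt <- stats::kruskal.test(v, factor(g))
  dir <- if (is.numeric(genotypes)) {
    means <- tapply(v, g, mean)
    sign(stats::coef(stats::lm(means ~ as.numeric(names(means))))[2])
  } else NA_real_
  assoc_result(unit, "kruskal_wallis", c(H = unname(kt$statistic)),
               kt$p.value, direction = unname(dir), n = length(v),
               group_summaries = group_summary(v, g),
               extra = list(df = unname(kt$parameter)))
}

#' Pairwise correlation matrix of CpG methylation
#'
#' Pairwise-complete correlation of the methylation block with two-sided
#' p-values (t-transform for Pearson; the same machinery for Spearman).
#' Entries with fewer than `min_pairs` complete pairs or a constant column
#' are left undefined (NA) and flagged, never silently zero.
#'
#' @param meth_block numeric matrix or data.frame, subjects x CpGs.
#' @param method `"pearson"` (default, matching the published matrix) or
#'   `"spearman"`.
#' @param min_pairs minimum complete pairs per entry.
#' @return List of matrices `r`, `p`, `n` plus logical `undefined`;
#'   `r` is symmetric with unit diagonal.
#' @export
correlation_matrix <- function(meth_block, method = c("pearson", "spearman"),
                               min_pairs = 3) {
  method <- match.arg(method)
  M <- as.matrix(meth_block)
  k <- ncol(M); nm <- colnames(M)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  n <- matrix(0L, k, k, dimnames = list(nm, nm))
  undef <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- stats::complete.cases(M[, c(i, j)])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < min_pairs || stats::sd(M[ok, i]) == 0 || stats::sd(M[ok, j]) == 0) {
      undef[i, j] <- undef[j, i] <- TRUE
      next
    }
    ct <- suppressWarnings(stats::cor.test(M[ok, i], M[ok, j], method = method))
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  if (any(undef)) warning("some correlation entries are undefined (constant column or too few pairs)")
  list(r = r, p = p, n = n, undefined = undef, method = method)
}

#' Linear age trend of methylation
#'
#' Least-squares regression of percent methylation on age: slope
#' (percent/year), Pearson correlation and its two-sided p-value.
#'
#' @param values numeric methylation values.
#' @param ages numeric ages in years.
#' @param unit label for the tested unit.
#' @return An `assoc_result` with statistic `slope`, correlation `r` in
#'   `extra`, and the two-sided p.
#' @export
age_trend <- function(values, ages, unit = "") {
  keep <- !is.na(values) & !is.na(ages)
  v <- values[keep]; a <- ages[keep]
  if (length(v) < 3) stop("age trend needs at least 3 complete observations")
  if (stats::sd(a) == 0) stop("age is constant; trend undefined")
  fit <- stats::lm(v ~ a)
  sm <- summary(fit)
  r <- stats::cor(a, v)
  assoc_result(unit, "age_trend",
               c(slope = unname(stats::coef(fit)[2])),
               sm$coefficients[2, 4],
               direction = sign(unname(stats::coef(fit)[2])), n = length(v),
               extra = list(r = r, intercept = unname(stats::coef(fit)[1]),
                            se_slope = sm$coefficients[2, 2]))
}

#' Age-adjusted logistic association of disease with methylation
#'
#' Maximum-likelihood logistic regression `disease ~ methylation + age`
#' (IRLS, deviance tolerance 1e-8, at most 50 iterations), reporting the
#' per-percent odds ratio with its Wald p-value. Perfect separation is
#' detected and raised as an error rather than returning divergent
#' coefficients.
#'
#' @param disease_labels two-level factor or logical/0-1 vector (TRUE/1 =
#'   case).
#' @param meth_values numeric percent methylation.
#' @param ages numeric ages.
#' @param unit label for the tested unit.
#' @return An `assoc_result` with statistic `log_or` (per percent), the
#'   Wald p, and `or`, `se`, age coefficient in `extra`.
#' @export
logistic_adjusted <- function(disease_labels, meth_values, ages, unit = "") {
  keep <- !is.na(disease_labels) & !is.na(meth_values) & !is.na(ages)
  y <- disease_labels[keep]
  if (is.factor(y) || is.character(y)) y <- as.integer(factor(y)) - 1L
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both disease classes must be present")
  x <- meth_values[keep]; a <- ages[keep]
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x + a, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete/quasi-complete separation: outcome perfectly ordered by the
  # linear predictor, or IRLS pushed fitted probabilities to 0/1
  eta <- fit$linear.predictors
  separated <- max(eta[y == 0]) <= min(eta[y == 1]) ||
               max(eta[y == 1]) <= min(eta[y == 0])
  if (separated || sep_warn)
    stop("perfect (or quasi-perfect) separation: effect estimates are not identifiable")
  if (!fit$converged) stop("logistic regression did not converge")
  sm <- summary(fit)
  assoc_result(unit, "logistic_adjusted",
               c(log_or = unname(stats::coef(fit)["x"])),
               sm$coefficients["x", 4],
               direction = sign(unname(stats::coef(fit)["x"])), n = length(y),
               extra = list(or = exp(unname(stats::coef(fit)["x"])),
                            se = sm$coefficients["x", 2],
                            age_log_or = unname(stats::coef(fit)["a"])))
}

#' Fisher exact test for a 2x2 contingency table
#'
#' Two-sided exact test: the p-value sums the hypergeometric probabilities
#' (margins fixed) of all tables whose probability does not exceed that of
#' the observed table; computed in log space, stable for cohort-scale
#' counts.
#'
#' @param tab 2x2 matrix of non-negative integer counts (all margins
#'   positive).
#' @param unit label for the tested unit.
#' @return An `assoc_result` with the conditional odds-ratio estimate and
#'   two-sided p.
#' @export
fisher_exact_2x2 <- function(tab, unit = "") {
  tab <- as.matrix(tab)
  if (!identical(dim(tab), c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  assoc_result(unit, "fisher_exact",
               c(odds_ratio = unname(ft$estimate)), ft$p.value,
               direction = sign(log(unname(ft$estimate))), n = sum(tab),
               extra = list(table = tab))
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' The published analysis reports raw p-values across the seven CpGs; an
#' optional false-discovery-rate column is provided for users who want it.
#'
#' @param p numeric p-values.
#' @return BH-adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
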