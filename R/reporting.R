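#' Per-CpG case-control association tests for a cohort
#'
#' Runs the two-sided Wilcoxon rank-sum comparison of percent methylation
#' between cases and controls at every CpG, returning one tidy row per
#' CpG. Optionally adds age-adjusted logistic regression results.
#'
#' @param tab cohort data.frame with exactly the case and control groups
#'   of interest.
#' @param control_label group label of the controls; every other label is
#'   treated as case.
#' @param logistic also fit `disease ~ methylation + age` per CpG.
#' @param bh add a Benjamini-Hochberg adjusted p column.
#' @return data.frame with columns `cpg`, per-group `n`/`mean`/`sd`,
#'   `w`, `p_wilcoxon`, `direction`, and optionally `or`, `p_logistic`,
#'   `p_bh`.
#' @export
cohort_associations <- function(tab, control_label = "control",
                                logistic = FALSE, bh = FALSE) {
  if (!control_label %in% tab$group)
    stop(sprintf("no subjects with control label '%s'", control_label))
  is_case <- tab$group != control_label
  if (!any(is_case)) stop("no case subjects in cohort")
  rows <- lapply(cpg_sites()$cpg, function(cpg) {
    v <- tab[[paste0("meth_", cpg)]]
    res <- wilcoxon_case_control(v[is_case], v[!is_case], unit = cpg)
    out <- data.frame(
      cpg = cpg,
      case_n = sum(is_case & !is.na(v)), case_mean = mean(v[is_case], na.rm = TRUE),
      case_sd = stats::sd(v[is_case][!is.na(v[is_case])]),
      control_n = sum(!is_case & !is.na(v)),
      control_mean = mean(v[!is_case], na.rm = TRUE),
      control_sd = stats::sd(v[!is_case][!is.na(v[!is_case])]),
      w = unname(res$statistic["W"]), p_wilcoxon = res$p_value,
      direction = res$direction, stringsAsFactors = FALSE)
    if (logistic) {
      lr <- logistic_adjusted(is_case, v, tab$age, unit = cpg)
      out$or <- lr$extra$or
      out$p_logistic <- lr$p_value
    }
    out
  })
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- adjust_bh(out$p_wilcoxon)
  out
}

#' Genotype-methylation (allele-specific methylation) association scan
#'
#' Kruskal-Wallis test of percent methylation across risk-allele count
#' groups for every requested SNP x CpG pair, on the case subset by
#' default (mirroring the published per-genotype boxplots in patients).
#'
#' @param tab cohort data.frame.
#' @param snps SNP ids to scan (genotype columns must be present).
#' @param group restrict to this group label; NULL = all subjects.
#' @return data.frame with one row per SNP x CpG: `snp`, `cpg`, `H`, `df`,
#'   `p`, `direction` (sign of mean trend over genotype), group means.
#' @export
asm_associations <- function(tab, snps = ins_snps(), group = NULL) {
  validate_cohort(tab, require_geno = snps)
  if (!is.null(group)) tab <- tab[tab$group %in% group, , drop = FALSE]
  if (!nrow(tab)) stop("no subjects selected for ASM analysis")
  rows <- list()
  for (sid in snps) {
    g <- tab[[paste0("geno_", sid)]]
    for (cpg in cpg_sites()$cpg) {
      v <- tab[[paste0("meth_", cpg)]]
      res <- kruskal_wallis_by_genotype(v, g, unit = sprintf("%s x %s", sid, cpg))
      means <- tapply(v[!is.na(g)], g[!is.na(g)], mean, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        snp = sid, cpg = cpg, H = unname(res$statistic["H"]),
        df = res$extra$df, p = res$p_value, direction = res$direction,
        mean_g0 = if ("0" %in% names(means)) means[["0"]] else NA_real_,
        mean_g1 = if ("1" %in% names(means)) means[["1"]] else NA_real_,
        mean_g2 = if ("2" %in% names(means)) means[["2"]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the paper-style per-CpG summary table
#'
#' One row per CpG with case and control mean +/- SD, the Wilcoxon p, and
#' hypomethylated-subject counts/percentages per group, plus one row for
#' the multi-CpG pattern with its Fisher exact p. Full precision is kept;
#' use [format_summary()] for display rounding.
#'
#' @param tab cohort data.frame (cases + controls).
#' @param flags a `flag_matrix` for the whole cohort with the pattern
#'   detected.
#' @param associations per-CpG association table from
#'   [cohort_associations()] on the same cohort.
#' @param control_label control group label.
#' @param pattern pattern name present in `flags$patterns`.
#' @return data.frame of class `summary_table`.
#' @export
summarize_cohort <- function(tab, flags, associations,
                             control_label = "control",
                             pattern = "triple_hypo") {
  stopifnot(inherits(flags, "flag_matrix"))
  if (!setequal(rownames(flags$hypo), tab$subject_id))
    stop("flag matrix and cohort cover different subjects")
  if (is.null(flags$patterns[[pattern]]))
    stop(sprintf("pattern '%s' missing from flag matrix", pattern))
  if (nrow(associations) == 0 || !all(associations$cpg %in% colnames(flags$hypo)))
    stop("association table does not match the classified CpGs")
  is_case <- flags$group[rownames(flags$hypo)] != control_label
  hypo <- flags$hypo
  rows <- merge(associations, data.frame(
    cpg = colnames(hypo),
    hypo_case_n = colSums(hypo[is_case, , drop = FALSE], na.rm = TRUE),
    hypo_control_n = colSums(hypo[!is_case, , drop = FALSE], na.rm = TRUE),
    stringsAsFactors = FALSE), by = "cpg", sort = FALSE)
  rows <- rows[match(associations$cpg, rows$cpg), ]
  n_case <- sum(is_case); n_control <- sum(!is_case)
  rows$hypo_case_pct <- 100 * rows$hypo_case_n / n_case
  rows$hypo_control_pct <- 100 * rows$hypo_control_n / n_control
  member <- flags$patterns[[pattern]]
  pat_case <- sum(member[is_case]); pat_control <- sum(member[!is_case])
  ptab <- matrix(as.integer(c(pat_case, pat_control,
                              n_case - pat_case, n_control - pat_control)), 2)
  p_pattern <- if (any(colSums(ptab) == 0)) NA_real_ else
    fisher_exact_2x2(ptab)$p_value
  prow <- data.frame(
    cpg = pattern,
    case_n = n_case, case_mean = NA_real_, case_sd = NA_real_,
    control_n = n_control, control_mean = NA_real_, control_sd = NA_real_,
    w = NA_real_, p_wilcoxon = NA_real_, direction = NA_real_,
    hypo_case_n = pat_case, hypo_control_n = pat_control,
    hypo_case_pct = 100 * pat_case / n_case,
    hypo_control_pct = 100 * pat_control / n_control,
    stringsAsFactors = FALSE)
  for (col in setdiff(names(rows), names(prow))) prow[[col]] <- NA
  out <- rbind(rows[, names(rows)], prow[, names(rows)])
  attr(out, "pattern") <- pattern
  attr(out, "p_pattern") <- p_pattern
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Format a summary table for display
#'
#' Means/SDs and percentages rounded to integers (matching the published
#' table formatting) and p-values floored at `< 2.2e-16` for display.
#'
#' @param s a `summary_table`.
#' @return A character data.frame ready for printing.
#' @export
format_summary <- function(s) {
  stopifnot(inherits(s, "summary_table"))
  fmt_ms <- function(m, sd) ifelse(is.na(m), "", sprintf("%d±%d", round(m), round(sd)))
  p <- ifelse(is.na(s$p_wilcoxon), "", format_p(s$p_wilcoxon))
  pat <- attr(s, "pattern")
  p[s$cpg == pat] <- format_p(attr(s, "p_pattern"))
  data.frame(
    unit = s$cpg,
    cases = fmt_ms(s$case_mean, s$case_sd),
    controls = fmt_ms(s$control_mean, s$control_sd),
    p = p,
    hypo_cases = sprintf("%d (%d%%)", s$hypo_case_n, round(s$hypo_case_pct)),
    hypo_controls = sprintf("%d (%d%%)", s$hypo_control_n, round(s$hypo_control_pct)),
    stringsAsFactors = FALSE)
}

#' Deterministic heatmap row/column ordering of a methylation block
#'
#' Agglomerative hierarchical clustering with Euclidean distance and
#' complete linkage (the defaults of the classic heatmap.2 display) on
#' complete cases. Rows are pre-sorted by subject id before clustering so
#' the leaf order is invariant to input row permutation (the documented
#' tie-break); no plot is produced, only orderings and merge heights.
#'
#' @param meth_block numeric matrix, subjects x CpGs, with subject ids as
#'   rownames.
#' @return List with `row_order` (subject ids in leaf order), `col_order`
#'   (CpG labels in leaf order), `row_heights`, `col_heights`
#'   (non-decreasing merge heights).
#' @export
heatmap_order <- function(meth_block) {
  M <- as.matrix(meth_block)
  M <- M[stats::complete.cases(M), , drop = FALSE]
  if (nrow(M) < 2) stop("heatmap ordering needs at least 2 complete rows")
  if (is.null(rownames(M))) rownames(M) <- sprintf("row%06d", seq_len(nrow(M)))
  M <- M[order(rownames(M)), , drop = FALSE]
  hr <- stats::hclust(stats::dist(M), method = "complete")
  hc <- stats::hclust(stats::dist(t(M[, order(colnames(M)), drop = FALSE])),
                      method = "complete")
  list(row_order = rownames(M)[hr$order],
       col_order = hc$labels[hc$order],
       row_heights = hr$height, col_heights = hc$height)
}

#' Run the full simulate/classify/associate/report pipeline
#'
#' Generates (or accepts) a cohort, fits the control reference, classifies
#' all subjects with the -2SD rule, detects the multi-CpG pattern, runs
#' the per-CpG case-control tests, the case CpG-CpG correlation matrix and
#' the genotype (ASM) scan, and writes a reproducible result bundle:
#' `cohort.tsv`, `reference.json`, `flags.tsv`, `associations.tsv`,
#' `asm.tsv`, `summary.tsv`, `results.json` and `log.json` (seed, config
#' hash, package and R versions). Re-running with identical inputs
#' reproduces identical numbers.
#'
#' @param x a `generator_config` or an existing cohort data.frame.
#' @param out_dir output directory (created; pass NULL to skip writing).
#' @param control_label control group label.
#' @param pattern_cpgs member CpGs of the disease signature.
#' @param seed seed override when `x` is a config.
#' @return Invisibly, a list with `cohort`, `reference`, `flags`,
#'   `associations`, `correlations`, `asm`, `summary`, `contingency`.
#' @export
run_pipeline <- function(x, out_dir = NULL, control_label = "control",
                         pattern_cpgs = c("m19", "m135", "m234"),
                         seed = NULL) {
  if (inherits(x, "generator_config")) {
    if (is.null(seed)) seed <- x$seed
    cohort <- generate_cohort(x, seed = seed)
    cfg <- x
  } else {
    cohort <- validate_cohort(x)
    cfg <- NULL
  }
  controls <- cohort[cohort$group == control_label, , drop = FALSE]
  cases <- cohort[cohort$group != control_label, , drop = FALSE]
  if (!nrow(controls)) stop(sprintf("no '%s' subjects to fit the reference on", control_label))
  ref <- fit_reference(controls, source_label = control_label)
  flags <- classify_subjects(cohort, ref)
  flags <- detect_pattern(flags, pattern_cpgs)
  case_flags <- detect_pattern(classify_subjects(cases, ref), pattern_cpgs)
  control_flags <- detect_pattern(classify_subjects(controls, ref), pattern_cpgs)
  contingency <- tryCatch(pattern_contingency(case_flags, control_flags),
                          error = function(e) NULL)
  assoc <- cohort_associations(cohort, control_label)
  corr <- correlation_matrix(as.matrix(
    cases[stats::complete.cases(cases[, meth_columns()]), meth_columns()]))
  dimnames(corr$r) <- dimnames(corr$p) <- list(cpg_sites()$cpg, cpg_sites()$cpg)
  asm <- tryCatch(asm_associations(cohort, group = unique(cases$group)),
                  error = function(e) NULL)
  summ <- summarize_cohort(cohort, flags, assoc, control_label)
  bundle <- list(cohort = cohort, reference = ref, flags = flags,
                 associations = assoc, correlations = corr, asm = asm,
                 summary = summ, contingency = contingency)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, cfg, seed)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir, cfg, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(bundle$cohort, file.path(out_dir, "cohort.tsv"))
  ref <- bundle$reference
  jsonlite::write_json(
    list(source_label = attr(ref, "source_label"),
         cpgs = as.data.frame(ref),
         thresholds = as.list(hypomethylation_threshold(ref))),
    file.path(out_dir, "reference.json"), auto_unbox = TRUE, digits = NA)
  flags_df <- data.frame(subject_id = rownames(bundle$flags$hypo),
                         group = unname(bundle$flags$group[rownames(bundle$flags$hypo)]),
                         bundle$flags$hypo,
                         check.names = FALSE, row.names = NULL)
  for (pn in names(bundle$flags$patterns))
    flags_df[[pn]] <- unname(bundle$flags$patterns[[pn]])
  utils::write.table(flags_df, file.path(out_dir, "flags.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(bundle$associations, file.path(out_dir, "associations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  if (!is.null(bundle$asm))
    utils::write.table(bundle$asm, file.path(out_dir, "asm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(format_summary(bundle$summary),
                     file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  jsonlite::write_json(
    list(summary = as.data.frame(bundle$summary),
         pattern_fisher_p = attr(bundle$summary, "p_pattern"),
         correlations = list(r = bundle$correlations$r,
                             p = bundle$correlations$p),
         contingency = if (!is.null(bundle$contingency)) list(
           table = bundle$contingency$table,
           p = bundle$contingency$fisher$p_value) else NULL),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = seed, config_hash = config_hash(cfg),
         config_name = if (!is.null(cfg)) cfg$name else NA,
         package_version = as.character(utils::packageVersion("insmeth")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, "log.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

# md5 of the canonical JSON serialization of a config (NULL -> NA)
config_hash <- function(cfg) {
  if (is.null(cfg)) return(NA_character_)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}
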