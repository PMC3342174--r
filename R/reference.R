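#' Fit a control reference distribution per CpG
#'
#' The hypomethylation classifier is anchored on the distribution of
#' percent methylation in non-diabetic controls: for each CpG the control
#' mean and sample standard deviation (n - 1 divisor) are recorded. The
#' reference must always be fit on a designated control subset, never on a
#' pooled case-control sample.
#'
#' @param controls cohort data.frame containing only reference (control)
#'   subjects.
#' @param cpgs CpG column labels to fit (default: all seven).
#' @param min_n minimum number of usable control values per CpG.
#' @param source_label identifier recorded with the model.
#' @return An object of class `reference_model`: a data.frame with one row
#'   per CpG (`cpg`, `mean`, `sd`, `n`) plus a `source_label` attribute.
#' @export
fit_reference <- function(controls, cpgs = cpg_sites()$cpg, min_n = 3,
                          source_label = "controls") {
  if (nrow(controls) == 0) stop("control cohort is empty")
  rows <- lapply(cpgs, function(cpg) {
    col <- paste0("meth_", cpg)
    if (!col %in% names(controls))
      stop(sprintf("control cohort lacks methylation column '%s'", col))
    v <- controls[[col]]
    v <- v[!is.na(v)]
    if (length(v) < min_n)
      stop(sprintf("CpG %s: only %d usable control values (< %d)",
                   cpg, length(v), min_n))
    s <- stats::sd(v)
    if (s == 0)
      stop(sprintf("CpG %s: zero variance in controls; reference undefined", cpg))
    data.frame(cpg = cpg, mean = mean(v), sd = s, n = length(v),
               stringsAsFactors = FALSE)
  })
  ref <- do.call(rbind, rows)
  attr(ref, "source_label") <- source_label
  class(ref) <- c("reference_model", "data.frame")
  ref
}

#' Hypomethylation threshold(s) of a reference model
#'
#' The classification rule flags a subject's CpG as relatively
#' hypomethylated when its value lies strictly below the control mean
#' minus two control standard deviations; this returns that threshold.
#'
#' @param ref a `reference_model`.
#' @param cpg CpG label(s); default all CpGs in the model.
#' @return Named numeric vector of thresholds (percent), `mean - 2 * sd`.
#' @export
hypomethylation_threshold <- function(ref, cpg = ref$cpg) {
  stopifnot(inherits(ref, "reference_model"))
  unknown <- setdiff(cpg, ref$cpg)
  if (length(unknown))
    stop(sprintf("CpG(s) not in reference model: %s", paste(unknown, collapse = ", ")))
  i <- match(cpg, ref$cpg)
  stats::setNames(ref$mean[i] - 2 * ref$sd[i], cpg)
}

#' Classify subjects against a reference model
#'
#' Flags each subject x CpG cell as hypomethylated when the value is
#' strictly below the -2SD threshold ("below" is read as strict: boundary
#' equality is not flagged). Missing methylation yields a missing flag.
#' Optionally a symmetric +2SD hypermethylation rule can be enabled; it is
#' off by default because only the hypomethylation rule defines the
#' disease signature.
#'
#' @param tab cohort data.frame to classify.
#' @param ref a `reference_model` covering the same CpG set.
#' @param hyper also compute +2SD hypermethylation flags.
#' @return An object of class `flag_matrix`: list with `hypo` (logical
#'   subjects x CpGs matrix, subject ids as rownames), `thresholds`,
#'   `group` (per-subject labels), `patterns` (named list, empty until
#'   [detect_pattern()]), and optionally `hyper`.
#' @export
classify_subjects <- function(tab, ref, hyper = FALSE) {
  stopifnot(inherits(ref, "reference_model"))
  cols <- paste0("meth_", ref$cpg)
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop(sprintf("cohort lacks CpG column(s) present in reference: %s",
                 paste(miss, collapse = ", ")))
  M <- as.matrix(tab[, cols, drop = FALSE])
  colnames(M) <- ref$cpg
  rownames(M) <- tab$subject_id
  thr <- hypomethylation_threshold(ref)
  hypo <- sweep(M, 2, thr, `<`)
  out <- list(hypo = hypo, thresholds = thr,
              group = stats::setNames(tab$group, tab$subject_id),
              patterns = list())
  if (hyper) {
    upper <- stats::setNames(ref$mean + 2 * ref$sd, ref$cpg)
    out$hyper <- sweep(M, 2, upper, `>`)
    out$upper_thresholds <- upper
  }
  structure(out, class = "flag_matrix")
}

#' Detect a multi-CpG hypomethylation pattern
#'
#' A subject carries the pattern iff every member CpG is flagged
#' hypomethylated and none is missing (subjects with incomplete
#' methylation are excluded from pattern membership). The canonical
#' disease signature is simultaneous hypomethylation of CpGs -19, -135
#' and -234.
#'
#' @param flags a `flag_matrix` from [classify_subjects()].
#' @param pattern_cpgs nonempty character vector of member CpG labels.
#' @param name pattern name used as the list key.
#' @return The `flag_matrix` with `patterns[[name]]` added: a logical
#'   per-subject membership vector, with per-group counts and integer
#'   percentages as attributes `counts` and `percent`.
#' @export
detect_pattern <- function(flags, pattern_cpgs, name = "triple_hypo") {
  stopifnot(inherits(flags, "flag_matrix"))
  if (length(pattern_cpgs) == 0) stop("pattern CpG set must be nonempty")
  unknown <- setdiff(pattern_cpgs, colnames(flags$hypo))
  if (length(unknown))
    stop(sprintf("pattern CpG(s) not classified: %s", paste(unknown, collapse = ", ")))
  sub <- flags$hypo[, pattern_cpgs, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0
  member <- complete & rowSums(sub, na.rm = TRUE) == length(pattern_cpgs)
  groups <- flags$group
  counts <- tapply(member, groups, sum)
  n <- tapply(member, groups, length)
  attr(member, "counts") <- data.frame(
    group = names(counts), members = as.integer(counts), n = as.integer(n),
    percent = as.integer(round(100 * as.integer(counts) / as.integer(n))),
    fraction = as.numeric(counts / n),
    stringsAsFactors = FALSE, row.names = NULL)
  flags$patterns[[name]] <- member
  flags
}

#' Case-control contingency table for a pattern
#'
#' Builds the 2x2 table of pattern members vs non-members across a case
#' and a control cohort (both classified against the same reference) and
#' attaches the two-sided Fisher exact p-value.
#'
#' @param case_flags,control_flags `flag_matrix` objects whose subject ids
#'   do not overlap, each carrying the pattern.
#' @param pattern pattern name.
#' @return List with `table` (2x2 integer matrix, rows cases/controls,
#'   columns member/non-member) and `fisher` (an `assoc_result`).
#' @export
pattern_contingency <- function(case_flags, control_flags, pattern = "triple_hypo") {
  for (f in list(case_flags, control_flags)) {
    stopifnot(inherits(f, "flag_matrix"))
    if (is.null(f$patterns[[pattern]]))
      stop(sprintf("pattern '%s' has not been detected on both cohorts", pattern))
  }
  if (length(intersect(rownames(case_flags$hypo), rownames(control_flags$hypo))))
    stop("case and control cohorts share subject ids")
  a <- sum(case_flags$patterns[[pattern]])
  b <- length(case_flags$patterns[[pattern]]) - a
  c_ <- sum(control_flags$patterns[[pattern]])
  d <- length(control_flags$patterns[[pattern]]) - c_
  tab <- matrix(as.integer(c(a, c_, b, d)), nrow = 2,
                dimnames = list(c("case", "control"), c("member", "non_member")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate contingency table: a margin is zero")
  list(table = tab, fisher = fisher_exact_2x2(tab))
}
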