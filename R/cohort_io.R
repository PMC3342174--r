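#' Validate a cohort table
#'
#' Enforces the cohort-table invariants: unique subject ids, non-negative
#' ages, sex coded M/F, percent methylation within \[0, 100\] (or NA),
#' genotypes coded as risk-allele counts 0/1/2 (or NA). Violations are
#' reported with the offending row and column.
#'
#' @param tab a data.frame in the cohort layout.
#' @param require_geno character vector of SNP ids whose genotype columns
#'   must be present (e.g. when an allele-specific methylation analysis is
#'   requested); default none.
#' @return `tab`, invisibly.
#' @export
validate_cohort <- function(tab, require_geno = character()) {
  req <- c("subject_id", "group", "age", "sex", meth_columns())
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop(sprintf("cohort is missing required column(s): %s",
                 paste(miss, collapse = ", ")))
  for (sid in require_geno) {
    col <- paste0("geno_", sid)
    if (!col %in% names(tab))
      stop(sprintf("genotype column '%s' is required for the requested analysis but absent", col))
  }
  if (anyDuplicated(tab$subject_id))
    stop(sprintf("duplicate subject_id: '%s'",
                 tab$subject_id[duplicated(tab$subject_id)][1]))
  bad_num <- function(col, ok) {
    v <- tab[[col]]
    if (!is.numeric(v)) stop(sprintf("column '%s' is not numeric", col))
    i <- which(!is.na(v) & !ok(v))
    if (length(i))
      stop(sprintf("invalid value %s in column '%s', row %d (subject '%s')",
                   format(v[i[1]]), col, i[1], tab$subject_id[i[1]]))
  }
  bad_num("age", function(v) v >= 0)
  for (col in intersect(meth_columns(), names(tab)))
    bad_num(col, function(v) v >= 0 & v <= 100)
  for (col in grep("^geno_", names(tab), value = TRUE))
    bad_num(col, function(v) v %in% c(0, 1, 2))
  i <- which(!is.na(tab$sex) & !tab$sex %in% c("M", "F"))
  if (length(i))
    stop(sprintf("invalid sex '%s' in row %d", tab$sex[i[1]], i[1]))
  invisible(tab)
}

#' Read a cohort table from a tab-separated file
#'
#' The dialect is tab-separated with a header row, `NA` as the missing
#' value token, canonical columns `subject_id`, `group`, `age`, `sex`,
#' `meth_m19` ... `meth_m234`, `geno_rs689` ... `geno_rs6356`, `hba1c`,
#' `duration` (CpG columns use an `m` prefix for negative TSS offsets to
#' keep identifiers sign-free). Unknown extra columns are carried through
#' untouched. The table is validated on read; malformed numbers and
#' out-of-range values are reported with row and column.
#'
#' @param path input TSV path.
#' @param require_geno SNP ids whose genotype columns must be present.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path, require_geno = character()) {
  if (!file.exists(path)) stop(sprintf("cohort file not found: %s", path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "NA", stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  num_cols <- intersect(c("age", meth_columns(), grep("^geno_", names(tab), value = TRUE),
                          "hba1c", "duration"), names(tab))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad))
      stop(sprintf("malformed number '%s' in column '%s', row %d",
                   tab[[col]][bad[1]], col, bad[1]))
    tab[[col]] <- v
  }
  validate_cohort(tab, require_geno = require_geno)
  tab
}

#' Write a cohort table to a tab-separated file
#'
#' Methylation percentages are serialized with 2 decimals; ages, HbA1c and
#' duration with 1 decimal; missing values as `NA`. Output bytes are
#' deterministic for a fixed table and round-trip through [read_cohort()]
#' up to the declared precision.
#'
#' @param tab a valid cohort data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  validate_cohort(tab)
  out <- tab
  fmt <- function(v, digits) ifelse(is.na(v), NA, formatC(v, format = "f", digits = digits))
  for (col in intersect(meth_columns(), names(out))) out[[col]] <- fmt(out[[col]], 2)
  for (col in intersect(c("age", "hba1c", "duration"), names(out)))
    out[[col]] <- fmt(out[[col]], 1)
  for (col in grep("^geno_", names(out), value = TRUE))
    out[[col]] <- ifelse(is.na(out[[col]]), NA, format(as.integer(out[[col]])))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Export cohort-mean methylation as a bedGraph track
#'
#' Writes one bedGraph interval per CpG with the cohort mean percent
#' methylation as the value. No genome build is bundled: the caller must
#' supply the genomic TSS coordinate, chromosome and strand. Intervals are
#' 0-based half-open of width 1; the CpG position is the TSS plus the
#' strand-signed offset (`tss + offset` on `+`, `tss - offset` on `-`).
#'
#' @param tab a valid cohort data.frame (nonempty).
#' @param tss_coordinate 0-based genomic coordinate of the TSS.
#' @param chrom chromosome name (e.g. `"chr11"`).
#' @param strand `"+"` or `"-"`.
#' @param path output path.
#' @param track_line include a UCSC track definition line.
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(tab, tss_coordinate, chrom, strand = c("+", "-"),
                            path, track_line = FALSE) {
  strand <- match.arg(strand)
  if (missing(tss_coordinate) || is.null(tss_coordinate) || is.na(tss_coordinate))
    stop("a genomic TSS coordinate is required (no genome build is bundled)")
  if (missing(chrom) || is.null(chrom)) stop("a chromosome name is required")
  validate_cohort(tab)
  if (nrow(tab) == 0) stop("empty cohort: refusing to write an empty track")
  sites <- cpg_sites()
  means <- vapply(paste0("meth_", sites$cpg),
                  function(col) mean(tab[[col]], na.rm = TRUE), 0)
  bed_start <- if (strand == "+") tss_coordinate + sites$offset
               else tss_coordinate - sites$offset
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = bed_start + 1, width = 1),
    score = unname(means))
  gr <- GenomicRanges::sort(gr)
  if (track_line) {
    line <- methods::new("BasicTrackLine", type = "bedGraph",
                         name = "INS promoter CpG methylation")
    rtracklayer::export.bedGraph(gr, path, trackLine = line)
  } else {
    rtracklayer::export.bedGraph(gr, path)
  }
  invisible(path)
}
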