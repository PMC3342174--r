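#' CpG and SNP metadata for the proximal INS promoter
#'
#' Seven CpG dinucleotides lie within ~250 bp upstream of the INS
#' transcription start site (TSS). Throughout the package they are
#' identified by sign-free column labels (`m19` for the CpG at TSS-relative
#' position -19, etc.); this table is the single mapping between column
#' labels, display labels and TSS-relative offsets.
#'
#' @return A data.frame with columns `cpg` (column label), `offset`
#'   (TSS-relative position in bp, negative = upstream) and `label`
#'   (display label, e.g. `"CpG -19"`).
#' @export
cpg_sites <- function() {
  offsets <- c(m19 = -19L, m69 = -69L, m102 = -102L, m135 = -135L,
               m180 = -180L, m206 = -206L, m234 = -234L)
  data.frame(cpg = names(offsets),
             offset = unname(offsets),
             label = sprintf("CpG %d", unname(offsets)),
             stringsAsFactors = FALSE)
}

#' SNPs of the INS locus used for allele-specific methylation analysis
#'
#' rs689 (A/T, +215 bp of the TSS; allele A tags short class I VNTR alleles
#' and T1D risk) and rs3842748 are promoter-proximal and in strong LD with
#' the VNTR; rs4320932 and rs6356 flank the locus at larger distance.
#'
#' @return Character vector of SNP identifiers in canonical order.
#' @export
ins_snps <- function() c("rs689", "rs3842748", "rs4320932", "rs6356")

# canonical cohort-table column order (the TSV dialect)
cohort_columns <- function() {
  c("subject_id", "group", "age", "sex",
    paste0("meth_", cpg_sites()$cpg),
    paste0("geno_", ins_snps()),
    "hba1c", "duration")
}

meth_columns <- function() paste0("meth_", cpg_sites()$cpg)
geno_columns <- function() paste0("geno_", ins_snps())
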