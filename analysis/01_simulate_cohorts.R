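#!/usr/bin/env Rscript
# Step 1 -- generate the two calibrated case-control cohorts.
#
# The T1D cohort (485 cases, 317 age-matched controls) and the T2D cohort
# (132 cases, 186 controls) are simulated from the shipped calibrations:
# per-group per-CpG marginal mean/SD on the percent scale, a Gaussian
# copula for the CpG-CpG correlation, LD-structured genotypes at
# rs689/rs3842748/rs4320932/rs6356 and additive rs689 effects at the four
# genotype-sensitive CpGs. Tables are written under results/ and a
# bedGraph track of control-mean methylation is exported against a
# user-supplied TSS coordinate (hg19 INS TSS, minus strand).

library(insmeth)
dir.create("results", showWarnings = FALSE)

t1d <- cohort_config("t1d_default")
t2d <- cohort_config("t2d_default")

tab1 <- generate_cohort(t1d)
tab2 <- generate_cohort(t2d)
write_cohort(tab1, "results/t1d_cohort.tsv")
write_cohort(tab2, "results/t2d_cohort.tsv")

cat(sprintf("T1D cohort: %d cases, %d controls\n",
            sum(tab1$group == "T1D"), sum(tab1$group == "control")))
cat(sprintf("T2D cohort: %d cases, %d controls\n",
            sum(tab2$group == "T2D"), sum(tab2$group == "control")))

# INS is on the minus strand of chr11; TSS coordinate supplied explicitly
# (hg19), no genome build is bundled with the package.
export_bedgraph(tab1[tab1$group == "control", ], tss_coordinate = 2182439,
                chrom = "chr11", strand = "-",
                path = "results/control_mean_methylation.bedGraph")
cat("wrote results/t1d_cohort.tsv, results/t2d_cohort.tsv and the bedGraph track\n")
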