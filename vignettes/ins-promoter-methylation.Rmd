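---
title: "Methods: case-control analysis of proximal INS promoter CpG methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control analysis of proximal INS promoter CpG methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

The insulin (*INS*) locus is the second-strongest genetic risk locus for
type 1 diabetes (T1D), tagged by the A/T SNP rs689 which in Europeans is in
complete linkage disequilibrium with the class I/III VNTR upstream of the
gene. `insmeth` analyses percent methylation, as read out by bisulfite
pyrosequencing, at the seven CpG dinucleotides of the proximal *INS*
promoter (TSS-relative positions −19, −69, −102, −135, −180, −206, −234;
column labels `m19` … `m234`). Its components are:

1. a **synthetic cohort generator** calibrated to published T1D and T2D
   case-control summaries, so that every downstream stage is testable
   without access to patient data;
2. a **reference-distribution hypomethylation classifier**: a subject's CpG
   is *relatively hypomethylated* when its value lies strictly below the
   control mean minus two control SDs, and the candidate T1D signature is
   the simultaneous hypomethylation of CpGs −19, −135 and −234;
3. **association statistics**: two-sided Wilcoxon rank-sum tests per CpG
   (cases vs controls), Kruskal–Wallis tests of methylation across
   genotype groups (allele-specific methylation), pairwise Pearson
   correlation with t-transform p-values, least-squares age trends,
   age-adjusted logistic regression, and the Fisher exact test for the
   signature's 2×2 case-control table;
4. **reporting**: the per-CpG summary table (mean ± SD, p, hypomethylated
   N (%)), deterministic hierarchical-clustering orderings for heatmap
   display, and a reproducible result bundle.

## The generator

Methylation is modelled as a clipped Gaussian copula on the percent scale.
For subject $i$ in group $g$ with genotype vector $g_{is}$ and age $a_i$,

$$
y_{ij} = \mu_{gj} + \sigma_{gj} z_{ij}
       + \sum_s \beta_{sj}\,(g_{is} - 2 f_s)
       + \gamma_j (a_i - \bar a), \qquad
z_i \sim \mathcal N(0, R_g),
$$

truncated to $[0, 100]$, where $\mu_{gj}, \sigma_{gj}$ are the configured
per-group marginal mean/SD (percent), $R_g$ the group's latent correlation
matrix, $\beta_{sj}$ the additive percent change per risk-allele copy,
$f_s$ the risk-allele frequency, and $\gamma_j$ an optional age slope
(percent/year). Two modelling choices deserve comment:

* **Clipped Gaussian, not logit-normal.** The published calibration targets
  are mean ± SD on the percent scale; a Gaussian marginal matches them
  directly. Clipping bias is negligible for most CpGs but real for CpG
  −206 (91 ± 5 in cases: about 3.6% of the mass would exceed 100); we
  accept and document this distortion rather than re-parameterize.
* **Centered genotype term.** The genotype effect enters as
  $\beta(g - 2f)$, centred at its population expectation, so the configured
  marginal mean *is* the population mean for any $\beta$. With an uncentred
  term the calibration targets would silently shift by $2f\beta$. The
  marginal SD is still interpreted as the noise scale, so a nonzero
  $\beta$ adds variance on top of $\sigma$; the fidelity guarantees below
  are therefore stated for the null-effect configuration.

Genotypes are built from two haplotypes per subject, each a thresholded
latent multivariate normal: allele = 1 iff $z < \Phi^{-1}(f)$. Because
thresholding changes correlations, the latent correlation for each SNP
pair is calibrated by root-finding on the bivariate normal CDF so the
*realized allele correlation* equals the configured `ld_r`; $|r| = 1$
(complete LD, the rs689–VNTR situation) is reproduced exactly by copying
the latent variable. A configuration whose pairwise `ld_r` entries are
jointly unattainable is rejected with the offending pair named.

One root seed drives everything; per-block sub-seeds (ages, sex,
genotypes, methylation, covariates) are derived from it by fixed offsets,
so adding a SNP perturbs only the genotype block. Generated methylation is
rounded to 2 decimals — the serialization precision of the cohort TSV —
which makes written bundles losslessly recomputable.

### Shipped calibrations

`t1d_default` encodes the published T1D study conditions: 485 cases vs 317
age-matched controls (ages ~12 ± 5 y, range 1–30), the per-CpG marginals
(e.g. CpG −135: 52 ± 9 in cases vs 68 ± 5 in controls), and HbA1c
(8.1 ± 1.4%) and diabetes duration (7.5 ± 8.5 y) for cases only, drawn
independently of methylation (no correlation with either was observed).
The case latent correlation matrix fixes the two published coefficients
(−19/−135 = 0.77, −135/−234 = 0.65) and fills the rest of the
−19/−135/−180/−234 block with values in the published 0.40–0.65 range;
the three genotype-sensitive-only CpGs (−69, −102, −206) are weakly
coupled (0.30 among themselves, 0.15 across). Control–control correlations
are not published beyond the statement that the coupling is also seen in
controls, so the control matrix **reuses the case matrix — a calibration
assumption**, not a reported value.

Genotype effects are unquantified in the source (boxplots only), so they
were fixed once at $\beta = +2$ percent per rs689 risk-allele copy at CpGs
−69/−102/−180/−206 and 0 at −19/−135/−234; rs3842748 carries no effect of
its own and mirrors rs689 purely through LD ($r = 0.9$), while the distant
flanking SNPs (rs4320932, rs6356) sit at $r = 0.2$. Allele frequencies
(rs689 A = 0.70, rs3842748 = 0.68, rs4320932 = 0.30, rs6356 = 0.40) are
typical European values. These choices reproduce the qualitative published
pattern — strong Kruskal–Wallis association at the four
genotype-sensitive CpGs for rs689 and rs3842748, none at the signature
CpGs, little for the distant SNPs — and were not tuned further.

`t2d_default` encodes the T2D comparison (132 cases vs 186 controls, ages
~54 ± 8): CpG −19 lower in cases as in T1D, CpG −234 *higher* (the
opposite direction), and a latent −19/−234 correlation of exactly 0, since
no correlation between those two changes was observed in T2D patients.
`aging_controls` enables the documented negative age trend (−0.15
percent/year at every CpG, ages 20–80) that the young T1D-study cohort
does not show; the young-cohort configs therefore keep all slopes at 0.

### What the generator does and does not emulate

It reproduces group sizes, marginal moments, CpG–CpG correlation, LD,
additive cis-genotype effects and age trends. It does **not** simulate
bisulfite conversion error, pyrogram peak heights, read-count noise, batch
effects, VNTR repeat lengths (LD to rs689 stands in for VNTR class), or
non-Gaussian features of real methylation distributions (skew, floor
effects, mixture structure). Consequently, passing calibration tests shows
the pipeline recovers what it assumes — not that real cohorts are
Gaussian. A visible instance: with Gaussian marginals the CpG −135 case
hypomethylation rate implied by (52 ± 9 vs threshold 58) is ~75%, whereas
the published cohort showed 56% — real case distributions are evidently
not Gaussian in the lower tail. Quantities computed from *printed counts*
(signature prevalence 14%, the 70/485 vs 0/317 Fisher p) are exact and do
not depend on the generator.

## Classification rules and conventions

* "Below −2SD" is a **strict** inequality; boundary equality is not
  flagged.
* The control SD uses the **n − 1 divisor** (the source does not state a
  divisor; the sample convention is standard for cohort summaries).
* The reference is always fit on a designated control subset of the same
  population; when no external reference is supplied, control subjects are
  classified **self-referentially** against their own sample's reference
  (whether the published control flag counts were computed this way is
  unstated; this is our decision).
* Pattern membership requires **complete** methylation at all member CpGs;
  a missing member value excludes the subject from the pattern (never
  counts toward it).
* Percentages are displayed rounded to the nearest integer, mirroring the
  published table (which itself mixes conventions — 8/317 shown as 2%);
  JSON outputs keep full precision.
* The summary table's pattern row is defined as CpGs **−19, −135, −234**:
  the published table labels that row "−19, −135, −180" but the text and
  abstract define the signature as −19/−135/−234, and we follow the text.
* Hypermethylation (the CpG −180 increase) is detected by the association
  statistics; a symmetric +2SD rule exists behind `hyper = TRUE` but is
  not part of the signature definition.

## Statistical choices

* **Wilcoxon rank-sum**: exact enumeration when both samples have ≤ 10
  observations without ties; otherwise the normal approximation with
  mid-ranks and tie-corrected variance, **continuity correction off** —
  this keeps the algebraic identity $H = z^2$ between the two-group
  Kruskal–Wallis chi-square p and the Wilcoxon normal-approximation p,
  which the tests verify to 1e-9.
* **Correlation**: the source's methods mention adjusted $R^2$ while its
  figures and abstract report signed $r$; we report signed **Pearson r**
  as primary (Spearman switchable), with two-sided t-transform p-values.
  Undefined entries (constant column, < 3 complete pairs) are flagged NA,
  never silently zero.
* **Fisher exact** is used for the signature 2×2 table; the source never
  names the test behind its p-value, and the two-sided exact conditional
  test is the defensible choice for a table with a zero cell. p sums
  hypergeometric probabilities ≤ the observed one and is stable at cohort
  scale (n ≈ 800).
* **Logistic regression** (disease ~ methylation + age) is fit by IRLS
  with deviance tolerance 1e-8 and ≤ 50 iterations; complete or
  quasi-complete separation (outcome perfectly ordered by the linear
  predictor, or fitted probabilities at 0/1) raises an explicit error
  instead of returning divergent coefficients.
* **Multiple testing**: raw p-values are reported across the seven CpGs,
  as in the source; a Benjamini–Hochberg column is available behind a
  flag. Displayed p-values are floored at `< 2.2e-16` (the R convention
  the source echoes); machine-readable output keeps the computed value.
* **Heatmap ordering**: agglomerative hierarchical clustering, Euclidean
  distance, complete linkage (the classic `heatmap.2` defaults); rows are
  pre-sorted by subject id before clustering, which makes the leaf order
  invariant to input permutation. Only orderings and merge heights are
  returned; plotting is left to the user.

## Numerical and degenerate-input handling

Correlation matrices must be symmetric, unit-diagonal and PSD to an
eigenvalue floor of −1e-8; matrices PSD only up to rounding are repaired
by eigenvalue clipping before the Cholesky factorization. Zero-variance
reference CpGs, empty groups, empty pattern sets, all-zero contingency
margins, constant ages, and single genotype groups are rejected with
informative errors. All-tied rank-test inputs return $H = 0, p = 1$
(Kruskal–Wallis) or $p = 1$ with a warning (Wilcoxon) rather than NaN.

## Problem sizes used by the test suite

The suite checks exactness by enumeration at small n (rank assignments for
$n_1+n_2 \le 10$; all 2×2 tables with fixed margins at $n \le 40$),
distributional calibration at moderate n (type-I error at $\alpha = 0.05$
over 2,000 null replicates; flag-rate convergence to $\Phi(-2) \approx
2.28\%$ on $10^5$ independent Gaussian controls), and cohort-scale
behaviour at the shipped sizes (485/317 and 132/186), with 25-replicate
medians for the simulated significance bounds. These sizes were chosen to
make each check statistically decisive at its stated tolerance while the
whole suite stays comfortably fast on a single CPU.

## Known limitations

* The Gaussian marginal model overstates tail rates for strongly shifted
  CpGs (see the −135 example above) and understates them near the 0/100
  boundaries where clipping engages.
* Group-level allele frequencies are shared between cases and controls;
  the rs689–T1D *genetic* association itself is not simulated, only the
  genotype–methylation (ASM) relationship within the cohort.
* The control correlation structure is assumed equal to the case
  structure (no published control values).
* Published p-values at non-signature CpGs (e.g. T2D CpG −135, p = 0.06)
  need not be reproduced by simulation from rounded marginals; only the
  signature significance bounds are treated as calibration targets.
* No genome build ships with the package: bedGraph export requires the
  user's TSS coordinate, chromosome and strand.
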