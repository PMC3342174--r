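# T1D case-control calibration: 485 cases vs 317 age-matched controls.
# Marginal percent-methylation means/SDs follow the published cohort
# summaries; the case latent correlation encodes the strong coupling of
# the T1D-associated CpGs (-19/-135 r=0.77, -135/-234 r=0.65, 0.40-0.65
# among -19/-135/-180/-234) with weaker correlation elsewhere; the control
# matrix reuses the case matrix (calibration assumption: the same coupling
# is seen in controls, no control values are published).
name: t1d_default
seed: 20120502
cpgs: [m19, m69, m102, m135, m180, m206, m234]
groups:
  - label: T1D
    "n": 485
    prop_male: 0.534
    age_mean: 12.1
    age_sd: 4.9
    mean: {m19: 54, m69: 90, m102: 73, m135: 52, m180: 69, m206: 91, m234: 54}
    sd:   {m19: 10, m69:  4, m102:  6, m135:  9, m180:  7, m206:  5, m234:  9}
    covariates:
      hba1c:    {mean: 8.1, sd: 1.4}
      duration: {mean: 7.5, sd: 8.5}
  - label: control
    "n": 317
    prop_male: 0.516
    age_mean: 11.8
    age_sd: 4.8
    mean: {m19: 64, m69: 89, m102: 73, m135: 68, m180: 66, m206: 91, m234: 62}
    sd:   {m19:  6, m69:  6, m102:  9, m135:  5, m180: 11, m206:  7, m234:  6}
latent_corr:
  T1D:
    - [1.00, 0.15, 0.15, 0.77, 0.45, 0.15, 0.60]
    - [0.15, 1.00, 0.30, 0.15, 0.15, 0.30, 0.15]
    - [0.15, 0.30, 1.00, 0.15, 0.15, 0.30, 0.15]
    - [0.77, 0.15, 0.15, 1.00, 0.45, 0.15, 0.65]
    - [0.45, 0.15, 0.15, 0.45, 1.00, 0.15, 0.40]
    - [0.15, 0.30, 0.30, 0.15, 0.15, 1.00, 0.15]
    - [0.60, 0.15, 0.15, 0.65, 0.40, 0.15, 1.00]
  control:
    - [1.00, 0.15, 0.15, 0.77, 0.45, 0.15, 0.60]
    - [0.15, 1.00, 0.30, 0.15, 0.15, 0.30, 0.15]
    - [0.15, 0.30, 1.00, 0.15, 0.15, 0.30, 0.15]
    - [0.77, 0.15, 0.15, 1.00, 0.45, 0.15, 0.65]
    - [0.45, 0.15, 0.15, 0.45, 1.00, 0.15, 0.40]
    - [0.15, 0.30, 0.30, 0.15, 0.15, 1.00, 0.15]
    - [0.60, 0.15, 0.15, 0.65, 0.40, 0.15, 1.00]
# rs689 A (risk) tags class I VNTR alleles; rs3842748 is in strong LD with
# it, the flanking SNPs only weakly. European allele frequencies.
snps:
  - {id: rs689,      risk_allele_freq: 0.70}
  - {id: rs3842748,  risk_allele_freq: 0.68}
  - {id: rs4320932,  risk_allele_freq: 0.30}
  - {id: rs6356,     risk_allele_freq: 0.40}
ld_r:
  - [1.0, 0.9, 0.2, 0.2]
  - [0.9, 1.0, 0.2, 0.2]
  - [0.2, 0.2, 1.0, 0.1]
  - [0.2, 0.2, 0.1, 1.0]
# additive percent-per-risk-allele effects: the rs689 A allele raises
# methylation of CpGs -69/-102/-180/-206 and leaves -19/-135/-234 flat;
# the rs3842748 association is carried entirely by LD with rs689.
beta:
  rs689: {m69: 2.0, m102: 2.0, m180: 2.0, m206: 2.0}
# young cohort (1-30 yr): no age trend of promoter methylation.
age_model:
  mean_age: 12.0
  sd_age: 4.85
  min_age: 1
  max_age: 30
  slope: {}
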