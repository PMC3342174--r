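# Older non-diabetic controls with a downward age trend of INS promoter
# methylation at every CpG, emulating the pattern reported in older adult
# control cohorts (the young T1D-study cohort shows essentially no trend).
name: aging_controls
seed: 20120504
cpgs: [m19, m69, m102, m135, m180, m206, m234]
groups:
  - label: control
    "n": 200
    prop_male: 0.5
    mean: {m19: 64, m69: 89, m102: 73, m135: 68, m180: 66, m206: 91, m234: 62}
    sd:   {m19:  6, m69:  6, m102:  9, m135:  5, m180: 11, m206:  7, m234:  6}
latent_corr:
  control:
    - [1.00, 0.15, 0.15, 0.77, 0.45, 0.15, 0.60]
    - [0.15, 1.00, 0.30, 0.15, 0.15, 0.30, 0.15]
    - [0.15, 0.30, 1.00, 0.15, 0.15, 0.30, 0.15]
    - [0.77, 0.15, 0.15, 1.00, 0.45, 0.15, 0.65]
    - [0.45, 0.15, 0.15, 0.45, 1.00, 0.15, 0.40]
    - [0.15, 0.30, 0.30, 0.15, 0.15, 1.00, 0.15]
    - [0.60, 0.15, 0.15, 0.65, 0.40, 0.15, 1.00]
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
beta:
  rs689: {m69: 2.0, m102: 2.0, m180: 2.0, m206: 2.0}
# -0.15 percent per year at every CpG over ages 20-80
age_model:
  mean_age: 50
  sd_age: 15
  min_age: 20
  max_age: 80
  slope: {m19: -0.15, m69: -0.15, m102: -0.15, m135: -0.15, m180: -0.15, m206: -0.15, m234: -0.15}
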