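# T2D case-control calibration: 132 non-obese T2D cases vs 186 age- and
# BMI-matched controls. Marginals follow the published T2D summaries
# (CpG -19 lower and CpG -234 higher in cases, the -234 direction opposite
# to T1D). The -19/-234 latent correlation is 0 (no correlation between
# the CpG -19 and CpG -234 changes was observed), other couplings modest.
name: t2d_default
seed: 20120503
cpgs: [m19, m69, m102, m135, m180, m206, m234]
groups:
  - label: T2D
    "n": 132
    prop_male: 0.5
    age_mean: 54
    age_sd: 8
    mean: {m19: 47, m69: 88, m102: 68, m135: 58, m180: 57, m206: 91, m234: 57}
    sd:   {m19: 11, m69: 11, m102: 18, m135: 10, m180: 19, m206: 10, m234:  9}
  - label: control
    "n": 186
    prop_male: 0.5
    age_mean: 54
    age_sd: 8
    mean: {m19: 54, m69: 88, m102: 64, m135: 55, m180: 61, m206: 93, m234: 51}
    sd:   {m19: 10, m69:  6, m102: 13, m135: 10, m180: 11, m206:  7, m234:  6}
latent_corr:
  T2D:
    - [1.00, 0.10, 0.10, 0.30, 0.30, 0.10, 0.00]
    - [0.10, 1.00, 0.20, 0.10, 0.10, 0.20, 0.10]
    - [0.10, 0.20, 1.00, 0.10, 0.10, 0.20, 0.10]
    - [0.30, 0.10, 0.10, 1.00, 0.30, 0.10, 0.30]
    - [0.30, 0.10, 0.10, 0.30, 1.00, 0.10, 0.30]
    - [0.10, 0.20, 0.20, 0.10, 0.10, 1.00, 0.10]
    - [0.00, 0.10, 0.10, 0.30, 0.30, 0.10, 1.00]
  control:
    - [1.00, 0.10, 0.10, 0.30, 0.30, 0.10, 0.00]
    - [0.10, 1.00, 0.20, 0.10, 0.10, 0.20, 0.10]
    - [0.10, 0.20, 1.00, 0.10, 0.10, 0.20, 0.10]
    - [0.30, 0.10, 0.10, 1.00, 0.30, 0.10, 0.30]
    - [0.30, 0.10, 0.10, 0.30, 1.00, 0.10, 0.30]
    - [0.10, 0.20, 0.20, 0.10, 0.10, 1.00, 0.10]
    - [0.00, 0.10, 0.10, 0.30, 0.30, 0.10, 1.00]
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
age_model:
  mean_age: 54
  sd_age: 8
  min_age: 30
  max_age: 65
  slope: {}
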