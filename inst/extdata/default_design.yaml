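# Default four-group synthetic study design: 57 subjects (14/17/14/12),
# 100 trials each, PVL-decay generating model, payoff escalation 0.1 per
# 10-card block. Equivalent to igtrl::default_study_design(seed = 2013).
seed: 2013
n_trials: 100
model: pvl_decay
escalation_rate: 0.1
groups:
  - label: "HIV+/DU+"
    n_subjects: 14
    age_mean: 43.3
    age_sd: 4.9
    param_means: {alpha: 0.38, lambda: 0.06, A: 0.20, c: 0.49}
    param_sds:   {alpha: 0.04, lambda: 0.01, A: 0.04, c: 0.40}
  - label: "HIV+/DU-"
    n_subjects: 17
    age_mean: 38.8
    age_sd: 8.3
    param_means: {alpha: 0.26, lambda: 0.25, A: 0.50, c: 0.55}
    param_sds:   {alpha: 0.02, lambda: 0.16, A: 0.19, c: 0.38}
  - label: "HIV-/DU+"
    n_subjects: 14
    age_mean: 40.6
    age_sd: 7.1
    param_means: {alpha: 0.36, lambda: 0.07, A: 0.21, c: 0.62}
    param_sds:   {alpha: 0.03, lambda: 0.01, A: 0.06, c: 0.38}
  - label: "HIV-/DU-"
    n_subjects: 12
    age_mean: 33.5
    age_sd: 8.5
    param_means: {alpha: 0.18, lambda: 1.84, A: 0.64, c: 0.36}
    param_sds:   {alpha: 0.02, lambda: 0.75, A: 0.18, c: 0.30}
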