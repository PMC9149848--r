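# Default latent trajectory class profiles for the synthetic cohort
# generator. Three classes: a large stable majority, a small class whose
# sustained-attention performance improves between waves, and a very small
# class with dramatic wave-3 deterioration in both attention and
# mobility/cognition. Weights 0.94/0.05/0.01 mirror the cluster proportions
# reported for community-dwelling older adults. Baseline covariate means and
# SDs follow published per-cluster descriptives; wave-3 shifts for the
# decliner class are strong enough to cross the clinical decline cut-offs
# (TUG 12 s, gait 100 cm/s, MMSE/MoCA 2 points).
stable:
  weight: 0.94
  lapse_rate_w1: 0.005
  lapse_rate_w3: 0.005
  p_mistake_lapsed: 0.70
  p_mistake_normal: 0.02
  rt_mean_w1: 377.0
  rt_mean_w3: 343.0
  rt_sd: 90.0
  covariate_base:        # wave-1 mean, sd
    tug:   [8.4, 1.6]
    ugs:   [138.2, 18.6]
    dtgs:  [113.9, 25.4]
    mmse:  [29.0, 1.5]
    moca:  [25.9, 2.7]
    age:   [60.6, 7.6]
  covariate_shift:       # additive wave-3 shift on the wave-1 value
    tug: 0.7
    ugs: -2.1
    dtgs: 1.3
    mmse: 0.0
    moca: 0.4
  falls_rate_w1: 0.3
  falls_rate_w3: 0.3
  p_female: 0.54
  education_probs: [0.16, 0.42, 0.42]   # primary/none, secondary, third/higher
  p_antihypertensives: 0.30
  p_diabetes: 0.05
  smoker_probs: [0.47, 0.40, 0.13]      # never, past, current
  drinking_probs: [0.79, 0.07, 0.14]    # no, don't know, yes
  ipaq_probs: [0.26, 0.36, 0.38]        # low, medium, high
improver:
  weight: 0.05
  lapse_rate_w1: 0.25
  lapse_rate_w3: 0.02
  p_mistake_lapsed: 0.70
  p_mistake_normal: 0.03
  rt_mean_w1: 460.0
  rt_mean_w3: 348.0
  rt_sd: 105.0
  covariate_base:
    tug:   [9.3, 2.3]
    ugs:   [129.5, 22.1]
    dtgs:  [102.1, 25.5]
    mmse:  [27.7, 2.6]
    moca:  [23.2, 4.0]
    age:   [65.8, 8.5]
  covariate_shift:
    tug: 0.8
    ugs: -3.4
    dtgs: -0.4
    mmse: 0.4
    moca: 0.1
  falls_rate_w1: 0.6
  falls_rate_w3: 0.3
  p_female: 0.59
  education_probs: [0.39, 0.37, 0.24]
  p_antihypertensives: 0.35
  p_diabetes: 0.06
  smoker_probs: [0.51, 0.36, 0.13]
  drinking_probs: [0.79, 0.11, 0.10]
  ipaq_probs: [0.31, 0.37, 0.32]
decliner:
  weight: 0.01
  lapse_rate_w1: 0.03
  lapse_rate_w3: 0.72
  p_mistake_lapsed: 0.75
  p_mistake_normal: 0.03
  rt_mean_w1: 423.0
  rt_mean_w3: 438.0
  rt_sd: 100.0
  covariate_base:
    tug:   [9.5, 2.3]
    ugs:   [126.7, 23.4]
    dtgs:  [100.8, 26.7]
    mmse:  [27.5, 2.5]
    moca:  [23.9, 4.2]
    age:   [68.7, 7.5]
  covariate_shift:
    tug: 2.5
    ugs: -25.0
    dtgs: -25.0
    mmse: -2.5
    moca: -2.5
  falls_rate_w1: 0.3
  falls_rate_w3: 0.8
  p_female: 0.41
  education_probs: [0.27, 0.49, 0.24]
  p_antihypertensives: 0.57
  p_diabetes: 0.14
  smoker_probs: [0.43, 0.43, 0.14]
  drinking_probs: [0.81, 0.05, 0.14]
  ipaq_probs: [0.27, 0.35, 0.38]
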