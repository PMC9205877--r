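# Default study configuration: a 19-subject, two-session (tVNS / sham)
# crossover on the iterated prisoner's dilemma, with diffusion-model
# generated choices and reaction times. All payoff cells, policy
# probabilities and effect calibrations live here, not in code.
task:
  payoff:
    cooperate_cooperate: 20
    cooperate_deceive: 0
    deceive_cooperate: 30
    deceive_deceive: 5
  enforce_dominance: true
  cooperative_p: 0.7
  deceitful_p: 0.3
  tft_first: mirror          # mirror | cooperate | deceive
  trials_per_opponent: 15
  time_limit_s: 10.0
  opponent_rt_min_s: 1.0
  opponent_rt_max_s: 3.0
cohort:
  n_subjects: 19
  age_mean: 45.0
  age_sd: 12.0
  age_min: 18.0
  age_max: 90.0
  female_p: 0.684            # 13 of 19
  believed_live_p: 0.632     # 12 of 19
  trait_mean:                # five-factor inventory domain scores
    neuroticism: 85.0
    extraversion: 110.0
    openness: 105.0
    agreeableness: 115.0
    conscientiousness: 120.0
  trait_sd:
    neuroticism: 20.0
    extraversion: 18.0
    openness: 17.0
    agreeableness: 16.0
    conscientiousness: 18.0
  trait_min: 0.0
  trait_max: 192.0
  panas_positive_mean: 17.6
  panas_positive_sd: 5.3
  panas_negative_mean: 18.4
  panas_negative_sd: 3.9
  disease_duration_mean: 18.0
  disease_duration_sd: 10.0
  seizure_free_mean: 6.0
  seizure_free_sd: 5.0
  medicated_p: 0.85
  sam_human_mean: 6.2        # planted human > computer likability offset
  sam_computer_mean: 4.7
  sam_sd: 1.5
  invalid_rate: 0.0035       # ~16 invalid trials in 4560
  effects:
    base_a: 1.6              # boundary separation, evidence units
    base_v: -0.327           # baseline drift (negative: towards deception)
    base_w: 0.5              # sham starting bias
    base_t0: 0.35            # non-decision time, s
    bias_shift_tvns: 0.03    # starting-bias increment under tVNS
    drift_shift_tvns: 0.085  # drift increment under tVNS (towards zero)
    neuroticism_modulation: -2.0   # attenuation of the bias shift per SD
    extraversion_modulation: 0.9   # amplification of the bias shift per SD
    subject_v_sd: 0.165      # between-subject drift SD
    session_v_sd: 0.075      # session-to-session drift SD
    reciprocity: 0.0         # drift penalty after being deceived (off)
    human_v_bonus: 0.0       # drift bonus against human opponents (off)
  sim:
    dt: 0.001                # Euler step, s
    bridge: false
    max_t_s: 20.0
fit:
  restarts: 5
  rt_floor_s: 0.2
  reltol: 1.0e-7
  quad_points: 7
  grouping: stim_condition
  min_trials: 20
stats:
  alpha: 0.05
  screen_r2: 0.7
  pilot_mean_diff: 9.2       # pilot anchors for the paired power computation
  pilot_sd: 10.0
  power: 0.95
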