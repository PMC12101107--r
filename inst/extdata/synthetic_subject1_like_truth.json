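{
  "baseline_rate": 1,
  "day_multiplier": 1.4,
  "circadian_amp": 0.1,
  "circadian_peak": 15,
  "semiseptan_amp": 0.3,
  "semiseptan_period": 90,
  "semiseptan_phase": -282,
  "noise_cv": 0.15,
  "night_noise_ratio": 1.25,
  "volume_day": 700,
  "volume_night": 500,
  "volume_cv": 0.15,
  "creatinine_day": 0.9,
  "creatinine_night": 1.35,
  "creatinine_cv": 0.1,
  "seed": 20041207,
  "inversion_target": 0.12208142230544
}
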