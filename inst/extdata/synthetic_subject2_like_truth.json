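{
  "baseline_rate": 0.8,
  "day_multiplier": 1.4,
  "circadian_amp": 0.1,
  "circadian_peak": 15,
  "semiseptan_amp": 0.2,
  "semiseptan_period": 90,
  "semiseptan_phase": -276,
  "noise_cv": 0.2,
  "night_noise_ratio": 1.25,
  "volume_day": 700,
  "volume_night": 500,
  "volume_cv": 0.15,
  "creatinine_day": 0.9,
  "creatinine_night": 1.35,
  "creatinine_cv": 0.1,
  "seed": 20060713,
  "inversion_target": 0.158541325780666
}
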