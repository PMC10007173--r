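{
  "n_frames_top": 60,
  "n_frames_front": 60,
  "n_paired": 60,
  "n_assessed": 60,
  "n_skipped": 0,
  "n_unmatched_top": 0,
  "n_unmatched_front": 0,
  "mean_fpa": 74.36564771,
  "min_fpa": 51.90184526,
  "letter_fractions": {
    "E": 0,
    "D": 0,
    "C": 0.05,
    "B": 0.6,
    "A": 0.35
  },
  "warning": {}
}
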