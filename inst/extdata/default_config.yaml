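calibration:
  top:
    frame_width_px: 1280.0
    frame_height_px: 720.0
    real_width_cm: 40.0
    real_height_cm: 22.5
  front:
    frame_width_px: 1280.0
    frame_height_px: 720.0
    real_width_cm: 40.0
    real_height_cm: 22.5
field:
  center_cm:
  - 20.0
  - 11.25
  front_field_band_cm:
  - 7.5
  - 15.0
fuzzy:
  defuzz_method: center_of_average
  distance:
    units: cm
    universe:
    - 0.0
    - 23.0
    labels:
      Close:
        shape: triangular
        breakpoints:
        - 0.0
        - 0.0
        - 11.5
      Middle:
        shape: triangular
        breakpoints:
        - 0.0
        - 11.5
        - 23.0
      Far:
        shape: triangular
        breakpoints:
        - 11.5
        - 23.0
        - 23.0
  height:
    units: cm
    universe:
    - 0.0
    - 22.5
    labels:
      High:
        shape: triangular
        breakpoints:
        - 0.0
        - 0.0
        - 11.25
      Field:
        shape: triangular
        breakpoints:
        - 0.0
        - 11.25
        - 22.5
      Down:
        shape: triangular
        breakpoints:
        - 11.25
        - 22.5
        - 22.5
  hand_score:
    units: percent
    universe:
    - 0.0
    - 100.0
    labels:
      E:
        shape: triangular
        breakpoints:
        - 0.0
        - 10.0
        - 30.0
      D:
        shape: triangular
        breakpoints:
        - 10.0
        - 30.0
        - 50.0
      C:
        shape: triangular
        breakpoints:
        - 30.0
        - 50.0
        - 70.0
      B:
        shape: triangular
        breakpoints:
        - 50.0
        - 70.0
        - 90.0
      A:
        shape: triangular
        breakpoints:
        - 70.0
        - 90.0
        - 100.0
  refuzzified:
    units: percent
    universe:
    - 0.0
    - 100.0
    labels:
      Bad:
        shape: trapezoidal
        breakpoints:
        - 0.0
        - 0.0
        - 10.0
        - 50.0
      Good:
        shape: triangular
        breakpoints:
        - 10.0
        - 50.0
        - 90.0
      Excellent:
        shape: trapezoidal
        breakpoints:
        - 50.0
        - 90.0
        - 100.0
        - 100.0
  final_score:
    units: percent
    universe:
    - 0.0
    - 100.0
    labels:
      E:
        shape: triangular
        breakpoints:
        - 0.0
        - 10.0
        - 30.0
      D:
        shape: triangular
        breakpoints:
        - 10.0
        - 30.0
        - 50.0
      C:
        shape: triangular
        breakpoints:
        - 30.0
        - 50.0
        - 70.0
      B:
        shape: triangular
        breakpoints:
        - 50.0
        - 70.0
        - 90.0
      A:
        shape: triangular
        breakpoints:
        - 70.0
        - 90.0
        - 100.0
  rules_level1:
  - height: High
    distance: Close
    grade: B
  - height: High
    distance: Middle
    grade: E
  - height: High
    distance: Far
    grade: E
  - height: Field
    distance: Close
    grade: A
  - height: Field
    distance: Middle
    grade: B
  - height: Field
    distance: Far
    grade: C
  - height: Down
    distance: Close
    grade: B
  - height: Down
    distance: Middle
    grade: B
  - height: Down
    distance: Far
    grade: D
  rules_level2:
  - right: Excellent
    left: Excellent
    grade: A
  - right: Excellent
    left: Good
    grade: B
  - right: Excellent
    left: Bad
    grade: C
  - right: Good
    left: Excellent
    grade: B
  - right: Good
    left: Good
    grade: C
  - right: Good
    left: Bad
    grade: E
  - right: Bad
    left: Excellent
    grade: C
  - right: Bad
    left: Good
    grade: D
  - right: Bad
    left: Bad
    grade: D
  symmetrize_level2: no
fusion:
  pairing_tolerance_s: 0.02
  min_score: 0.5
  hold_window_frames: 15.0
output:
  series: series.csv
  summary: summary.json
seed: 1.0
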