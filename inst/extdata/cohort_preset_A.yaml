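# Matched blood / bone-marrow cohort preset.
# 3/31 blood-positive (9.7%) and 25/31 marrow-positive (80.6%) matched
# patients; 13 additional marrow-only patients (10 positive).
n_matched: 31
n_marrow_only: 13
blood_igc_positive: 3
marrow_igc_positive: 25
marrow_only_igc_positive: 10
hazard_pos: 0.25      # per month; median PFS ~2.8 months
hazard_neg: 0.0833    # per month; median PFS ~8.3 months
censor_rate: 0.2
slide:
  width: 800
  height: 800
  pixelSize: 1.0
  backgroundLevel: 500
  noiseSd: 50
  wbcPerSlide: 500
  ctcPerSlide: 8
  igcPerPositive: 2
  segmentOffset: 2600     # ~1/3 of the planted signal contrast
  segmentMinArea: 20
  wbc:
    nucDiam: 7.0
    nucSd: 0.4
    cellDiam: 10.0
    cellSd: 0.5
    intensity: {DAPI: 8000, EPI: 0, CD45: 9000, VAR: 0}
  ctc:
    nucDiam: 12.0
    nucSd: 0.5
    cellDiam: 18.0
    cellSd: 1.0
    intensity: {DAPI: 8000, EPI: 9000, CD45: 0, VAR: 0}
  igc:
    nucDiam: 28.0
    nucSd: 1.0
    cellDiam: 36.0
    cellSd: 1.5
    intensity: {DAPI: 8000, EPI: 9000, CD45: 0, VAR: 0}
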