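# Example condition registry: the synthetic default, expressed in the
# loadable YAML format. Real analyses supply a jurisdiction-specific file
# with validated case definitions; code sets here are illustrative.
#
# match: "prefix" matches normalised codes by prefix (I50 matches I50.1),
# "exact" requires equality. A condition's rule is "any" (>= 1 qualifying
# code in the classification window, the default) or "amb2_or_hosp1"
# (>= 2 ambulatory claims or >= 1 hospital claim).
match: prefix
conditions:
  diabetes:
    codes: [E10, E11, "250"]
  chf:
    codes: [I50, "428"]
  copd:
    codes: [J44, "496"]
  ckd:
    codes: [N18, "585"]
  hypertension:
    codes: [I10, "401"]
  depression:
    codes: [F32, F33, "311"]
complexity_events:
  dialysis:
    codes: [Z49]
    condition: ckd
  home_oxygen:
    codes: [Z99.8]
    condition: copd
  cardiac_device:
    codes: [Z95]
    condition: chf
frailty_markers:
  frailty_care: [R54]
  palliative: [Z51.5]
  edmonton:
    dementia: [F03]
    incontinence: [R32]
    weight_loss: [R63.4]
    functional_dependence: [Z74.0]
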