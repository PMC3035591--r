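# Clinical-parameter transformations for the Bielefeld breast cancer project
# (BBCP) cohort: interval parameters are cut into the published categories;
# already-nominal parameters pass through. Bins are left-closed / right-open
# with the last bin unbounded above (so a BMI of exactly 25 is "overweight");
# the published ranges do not state boundary membership, this convention is
# the package default and can be overridden per column with `closed: right`.
columns:
  age:
    kind: interval_bins
    breaks: [0, 40, 50, 60, 70, 80]
    categories: [under 40, 40 to 49, 50 to 59, 60 to 69, 70 to 79, over 79]
  sample type:
    kind: passthrough
  BMI:
    kind: interval_bins
    breaks: [18.5, 25, 30]
    categories: [normal, overweight, obese]
  native country:
    kind: passthrough
  ethnic group:
    kind: passthrough
  nursing:
    kind: passthrough
  nursing period:
    kind: interval_bins
    breaks: [0, 1, 6, 15]   # months
    categories: [none, short, intermediate, long]
  menopause:
    kind: passthrough
  smoking:
    kind: passthrough
  alcohol:
    kind: passthrough
  sport:
    kind: interval_bins
    breaks: [0, 1, 5]       # hours per week
    categories: [nothing, little, plenty]
  sleep:
    kind: interval_bins
    breaks: [0, 7, 10]      # hours per day
    categories: [little, normal, plenty]
  familial breast cancer:
    kind: passthrough
  histology:
    kind: passthrough
  T:
    kind: passthrough
  N:
    kind: passthrough
  Grading:
    kind: passthrough
  Progesterone receptor IHC:
    kind: interval_bins
    breaks: [0, 2, 9]       # immunohistochemistry score 0..12
    categories: [negative, intermediate, high positive]
  Estrogen receptor IHC:
    kind: interval_bins
    breaks: [0, 2, 9]
    categories: [negative, intermediate, high positive]
  Her2-new:
    kind: passthrough
  intended operation:
    kind: passthrough
  inspection:
    kind: passthrough
  lateral acoustical shadow:
    kind: passthrough
  dorsal acoustic attenuation:
    kind: passthrough
  axilla:
    kind: passthrough
  tumor size:
    kind: interval_bins
    breaks: [0, 10, 26]     # millimetres on the mammogram
    categories: [small, intermediate, large]
  micro lime:
    kind: passthrough
  chemoregime:
    kind: passthrough
  herceptin treatment:
    kind: passthrough
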