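# Example registry override: a better-ventilated, lower greenhouse and a
# site-specific boom loading unit exposure. Unlisted constants keep their
# built-in values.
greenhouse:
  q: 5      # air changes per hour
  h: 3      # m
unit_exposures:
  - task_id: ml_boom
    formulation: liquid
    route: dermal
    value: 2.0          # mg per kg substance handled
    percentile: geometric_mean
    source: site-specific measurement campaign
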