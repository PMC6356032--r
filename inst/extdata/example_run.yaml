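# Reference maximize run: a non-volatile solid co-formulant assessed
# against a target RCR of 0.9 with no protective equipment.
substance:
  name: reference co-formulant
  physical_state: solid
  vapour_pressure: 0.001      # Pa
  dnel_worker_dermal: 3       # mg/kg bw/day
  dnel_worker_inhalation: 11  # mg/m3
  dnel_general_dermal: 1.5    # mg/kg bw/day
  dnel_general_inhalation: 2.6  # mg/m3
mode: maximize
target_rcr: 0.9
concentration: 0.25
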