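# Worked-example inputs: 800 published manuscripts in one year, the
# three-point resubmission distribution, and a 60/40 reviewer-effort split.
published:
  2015: 800
resubmission:
  exact: [0.05, 0.10, 0.85]
effort:
  probs:
    1: 0.6
    2: 0.4
parameters:
  d: 0.25
  r_s: 2.5
  beta: 0.9
  gamma: 0.20
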