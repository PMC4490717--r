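# Demonstration scenario: PI optical clamp of a small synthetic cultured
# network at 3 Hz/unit for 10 s.
plant:
  type: network
  n_units: 8
  spont_rate: 1.5
controller:
  type: pi
  K: 0.1
  Ti: 1.0
  Ts: 0.01
  tau: 2.5
schedule:
  times: [0]
  rates: [3]
duration: 10
seed: 1
pre_pulse: false
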