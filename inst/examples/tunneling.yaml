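# Stochastic-tunneling experiment: high-fitness mutant clone.
# With f_m = 3 the mutant fixates in ~96% of replicates; with f_m = 1.5
# tunneling essentially never occurs within this horizon.
N: 1000
M: 20000
n_total: 1000
params:
  f_h: 1
  f_c: 1.1
  f_m: 3
  r_m: 0.01
init:
  cancer: 100
  mutant: 0
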