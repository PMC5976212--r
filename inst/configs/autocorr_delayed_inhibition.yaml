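# Temporal decorrelation of a synthetic naturalistic movie under mixed
# feedback with fast excitation (5 ms loop delay) and slow inhibition
# (30 ms): emits stimulus and response autocorrelation curves.
task: autocorr
seed: 1
grid: {nx: 64, extent: 10, nt: 512, duration: 2000}
circuit:
  feedback: mixed
measure:
  window: 40
  max_lag: 50
  spatial_exponent: 2
  temporal_correlation: 0.9
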