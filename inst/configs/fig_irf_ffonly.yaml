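# Temporal impulse-response measures for a relay cell driven by feedforward
# excitation only (no interneuron inhibition, no cortical feedback): emits
# the biphasic index and peak response latency of the center-neuron trace.
task: irf
grid: {nx: 128, extent: 10, nt: 512, duration: 1000}
circuit:
  ff_inhibition: null
  feedback: none
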