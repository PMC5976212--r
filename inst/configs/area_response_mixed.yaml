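# Patch-grating area-response curve with mixed (narrow excitatory + broad
# inhibitory) cortical feedback; emits the suppression index and optimal
# stimulus size.
task: area_response
grid: {nx: 512, extent: 20, nt: 8, duration: 16}
circuit:
  feedback: mixed
measure:
  kind: patch_grating
  k_mag: 0.9424778
  diameters: {from: 0.2, to: 10, by: 0.2}
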