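# Example run configuration: tremor-band network with the STN->GPe weight
# raised to its switching value, stimulated in the STN.
preset: tremor
w7: 22
simulation:
  duration: 4
  integrator: rk4
dbs:
  target: STN
  amplitude: 5
  frequency: 120
spectral:
  resolution: 0.25
bands:
  tremor: [3, 8]
  beta: [13, 30]
  gamma: [30, 90]
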