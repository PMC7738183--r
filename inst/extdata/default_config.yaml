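scenario: untreated
seed: 1
stages:
  doseresponse: yes
  sizing: yes
  fcs: yes
  lipids: yes
  depletion: yes
  secretion: yes
  tirf: no
doseresponse:
  calciumLevels:
  - 4.0
  - 9.0
  - 13.0
  - 18.0
  - 24.0
  - 32.0
  - 45.0
  - 300.0
  nGranules: 300.0
sizing:
  nDiameters: 2000.0
  mixtureK: 2.0
fcs:
  nRuns: 3.0
  curvesPerRun: 20.0
  noise: 0.01
  omegaR: 2.0e-07
  structure: 5.0
  temperature: 295.15
lipids:
  nReps: 4.0
  cv: 0.15
depletion:
  noiseSd: 0.3
tirf:
  nGranules: 24.0
  shape:
  - 96.0
  - 96.0
  nFrames: 160.0
  calcium: 100.0
  psfSigma: 1.2
  background: 100.0
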