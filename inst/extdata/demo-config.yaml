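# Example configuration for runDemo()/validateConfig().
# seed is mandatory; any key not listed in the defaults is rejected.
mode: full-demo
seed: 1
outputDir: demo-out
trimFraction: 0.4
contactCutoff: 4.5
alpha: 0.05
foldAsymmetry: 2.4
noiseSd: 0.02
timepoints: [0, 2, 5, 10, 15, 20, 30, 50]
replicates: 3
trajFrames: 120
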