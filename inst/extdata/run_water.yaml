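# Example run configuration for a pure-water CFCMC simulation.
seed: 20240301
temperature: 300 K
pressure: 1 bar
counts: {H2O: 100}
density: 997          # starting mass density, kg/m3
nsteps_equil: 1000000
nsteps_prod: 2000000
nblocks: 5
move_weights: [0.35, 0.35, 0.02, 0.18, 0.10]
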