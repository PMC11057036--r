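# Four-site rigid water: TIP4P/2005 geometry and LJ, PES charges for
# sampling, ECS charges (PES x 0.965) for free-energy evaluation.
# Units: nm, kJ/mol, elementary charge, g/mol.
species:
  - name: H2O
    sites:
      - {name: O,  sigma: 0.31589, epsilon: 0.7749, q_pes: 0.0,
         q_ecs: 0.0, xyz: [0.0, 0.0, 0.0], mass: 15.999}
      - {name: H1, sigma: 0.0, epsilon: 0.0, q_pes: 0.5564,
         q_ecs: 0.536926, xyz: [0.075695, 0.0, 0.058588], mass: 1.008}
      - {name: H2, sigma: 0.0, epsilon: 0.0, q_pes: 0.5564,
         q_ecs: 0.536926, xyz: [-0.075695, 0.0, 0.058588], mass: 1.008}
      - {name: M,  sigma: 0.0, epsilon: 0.0, q_pes: -1.1128,
         q_ecs: -1.073852, xyz: [0.0, 0.0, 0.01546], mass: 0.0}
fractional_group:
  composition: {H2O: 1}
  surface: ECS
cutoff: 0.9
ewald_accuracy: 1.0e-5
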