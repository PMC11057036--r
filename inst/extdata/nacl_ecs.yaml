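# Scaled-charge NaCl ion pair (0.85 e convention) with the ECS ion charges
# (+0.95/-0.95 e). LJ self-parameters follow the published scaled-charge
# NaCl model; bespoke ion-water cross terms are NOT bundled here and should
# be supplied as pair_overrides when combining with water.
species:
  - name: Na+
    net_charge: 0.85
    sites:
      - {name: Na, sigma: 0.221737, epsilon: 1.472356, q_pes: 0.85,
         q_ecs: 0.95, xyz: [0.0, 0.0, 0.0], mass: 22.990}
  - name: Cl-
    net_charge: -0.85
    sites:
      - {name: Cl, sigma: 0.469906, epsilon: 0.076923, q_pes: -0.85,
         q_ecs: -0.95, xyz: [0.0, 0.0, 0.0], mass: 35.453}
fractional_group:
  composition: {Na+: 1, Cl-: 1}
  surface: ECS
cutoff: 0.9
ewald_accuracy: 1.0e-5
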