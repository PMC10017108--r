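# Calibrated kinetic constants: EAAT1 (glutamate transporter, forward
# transport mode). Units as in asct2_wt.yaml. Calibration anchors:
# glutamate-application transient anion-current decay tau ~11 ms;
# paired-pulse recovery tau ~95 ms (empty-carrier relocation limited);
# slow-equilibrating allosteric inhibitor (k_off time constant ~100 s,
# K_U = 0.6 uM) with full block when bound (alpha = 0, no residual
# conductance).
name: eaat1
states: [OutApo, OutNa, OutNa2, OutLoaded, InLoaded, InApo]
transitions:
  - {from: OutApo,    to: OutNa,     k0_forward: 100,  k0_reverse: 100,  ligand: Na_out, z_delta: 0.25, type: binding}
  - {from: OutNa,     to: OutNa2,    k0_forward: 100,  k0_reverse: 1000, ligand: Na_out, z_delta: 0.25, type: binding}
  - {from: OutNa2,    to: OutLoaded, k0_forward: 10,   k0_reverse: 200,  ligand: S_out,  z_delta: 0,    type: binding}
  - {from: OutLoaded, to: InLoaded,  k0_forward: 80,   k0_reverse: 10,   ligand: none,   z_delta: 0.4,  type: translocation}
  - {from: InApo,     to: InLoaded,  k0_forward: 0.05, k0_reverse: 500,  ligand: S_in,   z_delta: 0,    type: binding}
  - {from: InApo,     to: OutApo,    k0_forward: 10.6, k0_reverse: 0.5,  ligand: none,   z_delta: 0.2,  type: translocation}
inhibitor: {k_on: 0.01667, k_off: 0.01, alpha: 0, conductance_scale: 0}
conducting_weights: {OutLoaded: 1.0, InLoaded: 0.3}
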