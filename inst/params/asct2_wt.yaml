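# Calibrated kinetic constants: wild-type ASCT2 (neutral amino acid
# exchanger, homo-exchange mode). Units: /s; ligand-tagged forward rates
# /s/uM (substrate, inhibitor) or /s/mM (Na+); z_delta in elementary
# charges. Calibration anchors: exchange recovery tau ~15 ms at zero
# inhibitor; apparent serine Km ~280 uM; fast-equilibrating allosteric
# inhibitor with K_U = 77 uM, full block of translocation when bound
# (alpha = 0) but partial residual anion conductance of bound states
# (conductance_scale = 0.55).
name: asct2_wt
states: [OutApo, OutNa, OutNa2, OutLoaded, InLoaded, InApo]
transitions:
  - {from: OutApo,    to: OutNa,     k0_forward: 100,  k0_reverse: 100,  ligand: Na_out, z_delta: 0.25, type: binding}
  - {from: OutNa,     to: OutNa2,    k0_forward: 100,  k0_reverse: 1000, ligand: Na_out, z_delta: 0.25, type: binding}
  - {from: OutNa2,    to: OutLoaded, k0_forward: 10,   k0_reverse: 2800, ligand: S_out,  z_delta: 0,    type: binding}
  - {from: OutLoaded, to: InLoaded,  k0_forward: 150,  k0_reverse: 80,   ligand: none,   z_delta: 0.4,  type: translocation}
  - {from: InApo,     to: InLoaded,  k0_forward: 0.5,  k0_reverse: 1000, ligand: S_in,   z_delta: 0,    type: binding}
  - {from: InApo,     to: OutApo,    k0_forward: 0.0001, k0_reverse: 0.0001,    ligand: none,   z_delta: 0.1,  type: translocation}
inhibitor: {k_on: 25.974, k_off: 2000, alpha: 0, conductance_scale: 0.55}
conducting_weights: {OutLoaded: 1.0, InLoaded: 1.0}
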