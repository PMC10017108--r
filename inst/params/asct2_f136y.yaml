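# Calibrated kinetic constants: ASCT2 F136Y mutant. Identical to wild
# type except the serine dissociation constant, raised so the apparent
# Km is ~790 uM, and the allosteric site, which blocks fully when
# occupied (K_U = 30 uM assumed; the mutant's inhibition constant is
# not a calibration anchor).
name: asct2_f136y
states: [OutApo, OutNa, OutNa2, OutLoaded, InLoaded, InApo]
transitions:
  - {from: OutApo,    to: OutNa,     k0_forward: 100,  k0_reverse: 100,  ligand: Na_out, z_delta: 0.25, type: binding}
  - {from: OutNa,     to: OutNa2,    k0_forward: 100,  k0_reverse: 1000, ligand: Na_out, z_delta: 0.25, type: binding}
  - {from: OutNa2,    to: OutLoaded, k0_forward: 10,   k0_reverse: 7900, ligand: S_out,  z_delta: 0,    type: binding}
  - {from: OutLoaded, to: InLoaded,  k0_forward: 150,  k0_reverse: 80,   ligand: none,   z_delta: 0.4,  type: translocation}
  - {from: InApo,     to: InLoaded,  k0_forward: 0.5,  k0_reverse: 1000, ligand: S_in,   z_delta: 0,    type: binding}
  - {from: InApo,     to: OutApo,    k0_forward: 0.0001, k0_reverse: 0.0001,    ligand: none,   z_delta: 0.1,  type: translocation}
inhibitor: {k_on: 33.333, k_off: 1000, alpha: 0, conductance_scale: 0}
conducting_weights: {OutLoaded: 1.0, InLoaded: 1.0}
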