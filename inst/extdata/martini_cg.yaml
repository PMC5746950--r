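# Default coarse-grain force-field parameter tables for lnpsim.
#
# The values below are documented Martini-2.0-like magnitudes: sigma 0.47 nm
# for regular bead pairs (0.43 nm between fine-mapped ring beads, with the
# ring epsilon scaled down), epsilon levels graded by polarity spanning
# roughly 2.0-5.6 kJ/mol, chain bonds r0 = 0.47 nm with k = 1250
# kJ mol^-1 nm^-2 and chain angles theta0 = 180 deg with k = 25 kJ/mol.
# They reproduce the qualitative interaction ordering of published Martini
# tables (hydrophobic beads attract each other more strongly than they
# attract water); users wanting a specific published parameter set can edit
# this file or supply their own.
version: 1
units:
  length: nm
  energy: kJ/mol
  mass: amu
bead_types: [C1, Na, P3, P4, AF]
mass: 72
lj:
  default_sigma: 0.47
  ring_sigma: 0.43
  ring_eps_scale: 0.75
  # epsilon in kJ/mol; upper triangle, symmetrised on load
  epsilon:
    C1: {C1: 3.5, Na: 2.7, P3: 2.3, P4: 2.0, AF: 2.0}
    Na: {Na: 4.0, P3: 4.0, P4: 4.0, AF: 4.0}
    P3: {P3: 4.0, P4: 4.5, AF: 4.5}
    P4: {P4: 5.6, AF: 5.6}
    AF: {AF: 5.6}
  # pairwise sigma overrides (nm); the enlarged AF-P4 size is the
  # antifreeze mechanism that frustrates crystallisation of the water bead
  # lattice
  sigma_overrides:
    P4: {AF: 0.57}
bonded:
  bond: {r0: 0.47, k: 1250}          # k in kJ mol^-1 nm^-2
  angle: {theta0: 180, k: 25}        # cosine-harmonic, k in kJ/mol
  ring_bond: {r0: 0.33, k: 20000}    # stiff bonds holding ring geometry
  ring_diagonal: {k: 2000}           # cross-ring distance restraints
water:
  af_per_p4: 0.1                     # one antifreeze bead per ten P4 beads
  waters_per_p4: 4                   # real water molecules per P4 bead
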