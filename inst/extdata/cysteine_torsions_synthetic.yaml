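# Five main internal rotations of the cysteine seed geometry
# (cysteine_seed_synthetic.xyz; atom indices are 1-based rows of that file).
# This torsion assignment is a best-effort reconstruction for the packaged
# synthetic seed, not a published definition.
torsions:
  - name: thiol
    dihedral_atoms: [8, 1, 2, 3]   # H-S-C(beta)-C(alpha)
    moving_set: [8]
    step: 60
    symmetry_period: 360
  - name: sidechain
    dihedral_atoms: [1, 2, 3, 5]   # S-C(beta)-C(alpha)-C(carboxyl)
    moving_set: [1, 8, 9, 10]
    step: 60
    symmetry_period: 360
  - name: amino
    dihedral_atoms: [2, 3, 4, 12]  # C(beta)-C(alpha)-N-H
    moving_set: [12, 13]
    step: 60
    symmetry_period: 360
  - name: carboxyl
    dihedral_atoms: [4, 3, 5, 6]   # N-C(alpha)-C-O(carbonyl)
    moving_set: [6, 7, 14]
    step: 60
    symmetry_period: 360
  - name: hydroxyl
    dihedral_atoms: [6, 5, 7, 14]  # O(carbonyl)-C-O-H
    moving_set: [14]
    step: 60
    symmetry_period: 360
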