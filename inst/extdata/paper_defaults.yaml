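# Default analysis profile: binding-site residue ranges, groove
# compartments, interaction criteria, entropy and SIE settings.
seed: 1
frame_interval: 200        # ps between frames (600 frames span 120 ns)
selections:
  binding_site:
    alpha: [5, 76]
    beta: [5, 90]
compartments:
  D1: {alpha: [50, 51], beta: [85, 86]}
  D2: {alpha: [53, 55], beta: [78, 83]}
  D3: {alpha: [60, 65], beta: [65, 70]}
  D4: {alpha: [68, 73], beta: [56, 61]}
criteria:
  hbond:
    da_cutoff: 3.1         # Angstrom, donor-acceptor
    angle_cutoff: 130      # degrees, donor-H-acceptor minimum
    persistence_threshold: 0.2
  stacking:
    dihedral_cutoff: 30    # degrees between ring planes
    centroid_cutoff: 5.0   # Angstrom between ring centroids
    persistence_threshold: 0.2
  hydrophobic:
    contact_cutoff: 4.0    # Angstrom, side-chain heavy atoms
    water_exclusion_radius: 4.0
    persistence_threshold: 0.2
histogram:
  rmsd_bin_width: 0.1      # Angstrom
  width_bin_width: 0.25    # Angstrom
entropy:
  temperature: 310         # K
sie:
  enabled: true
  alpha: 0.1048
  d_in: 2.25
  gamma: 0.0129            # kcal/(mol A^2)
  constant: -2.89          # kcal/mol
  temperature: 310
  stride_ps: 20
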