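# Example run configuration for `strucdiff compare --config=...` /
# run_comparison().  Compares an "open" complex (numerator) against a
# "closed" one (denominator): per-residue SASA, residue pairing, the
# differential fold-bin table, interface restriction, cavities, and
# point measurements.  Named region selections play the role of
# TM6/TM7/H8/switch-II definitions; residue ranges are configuration,
# never hard-coded.
structures:
  a: open.pdb
  b: closed.pdb
chain_pairs:       # chain in a -> analogous chain in b
  A: A
  B: B
sasa:
  probe_radius: 1.4
  n_points: 960
  include_hetero: false
diff:
  exclusion_delta: 2.5          # percentage points of relative SASA
  ratio_mode: relative_percent
cavity:
  grid_spacing: 0.5
  probe_radius: 1.4
  detection_multiplier: 3       # detection radius, in solvent radii
  cutoff_multiplier: 4          # cavity cutoff, in solvent radii
contacts:
  cutoff: 4.0
selections:
  receptor: chain A
  partner: chain B
  tm_tip: chain A and resno 36-40
interface:                      # restrict the fold-bin table to
  structure: b                  # residues in contact in structure b
  sel_a: receptor
  sel_b: partner
measurements:
  distances:
    - structure: a
      from: {chain: A, resno: 2}
      to: {chain: A, resno: 9}
  contacts:
    - structure: b
      sel_a: receptor
      sel_b: partner
output_dir: strucdiff_out
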