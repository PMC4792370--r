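# Canonical preset "Sample 1": 0.01-molar electrolyte, effective ion charge
# 3e with inner permittivity folded in (eps = 1, q = 3e), effective ion mass
# 1e4 electron masses. The bulk plasmon frequency is pinned to the canonical
# 9.3e13 rad/s via the override field. Nominal radius 1 um (micrometre-scale
# membrane-bounded compartment); sweep operations supply their own radius
# grids.
name: sample1
operation: damping
system:
  radius_m: 1.0e-6
  outer_permittivity: 2
  boundary_C: 2
  dof_factor: 3
  plasma_frequency_override_per_s: 9.3e+13
  ion:
    charge_number_e: 3
    effective_mass_me: 1.0e+4
    label: effective ion, Sample 1
  electrolyte:
    molarity_mol_per_L: 1.0e-2
    inner_permittivity: 1
    temperature_K: 300
    mean_free_path_m: 1.0e-7
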