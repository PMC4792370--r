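# Canonical preset "Sample 2": 0.001-molar electrolyte, same effective ion
# (charge 3e, mass 1e4 m_e), longer bulk mean free path (0.3 um), bulk
# plasmon frequency pinned to 2.93e12 rad/s.
name: sample2
operation: damping
system:
  radius_m: 1.0e-6
  outer_permittivity: 2
  boundary_C: 2
  dof_factor: 3
  plasma_frequency_override_per_s: 2.93e+12
  ion:
    charge_number_e: 3
    effective_mass_me: 1.0e+4
    label: effective ion, Sample 2
  electrolyte:
    molarity_mol_per_L: 1.0e-3
    inner_permittivity: 1
    temperature_K: 300
    mean_free_path_m: 3.0e-7
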