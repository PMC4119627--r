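# Example simulation configuration. Units: mm, N, N/mm^2 internally; the
# expander pressure below is given in the conventional N/cm^2 and converted
# at this boundary (30 N/cm^2 = 0.3 N/mm^2).
material:
  a: 0.1        # N/mm^2, exponential prefactor (shear-modulus scale)
  b: 10         # dimensionless strain-stiffening rate
  kappa: 10     # N/mm^2, volumetric penalty (default 100 * a)
expander:
  axis_ratio: [1.53, 1, 1]
  pressure: 30
  pressure_unit: N/cm2
  target_volume: 200000   # mm^3 (200 mL), grown linearly over the steps
solver:
  n_steps: 8
  rtol: 1.0e-8
  max_iter: 30
planning:
  defect_area: 4266.04    # mm^2
  shrinkage: 0.30
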