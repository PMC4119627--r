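# Published clinical scalp-expansion case: per-step surface area and head
# volume measured on an 8-step simulation of an adult patient, used here as
# reference input for the planning arithmetic. The defect area was estimated
# pre-operatively by Delaunay triangulation of sampled surface points.
defect_area_mm2: 4266.04
shrinkage: 0.30
n_steps: 8
area_series: clinical_step_areas.csv
volume_series: clinical_step_volumes.csv
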