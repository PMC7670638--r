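# Example pipeline configuration: 4-subject smoke cohort on a 24^3 grid.
outdir: out
seed: 7
phantom: two_compartment
phantom_args:
  shape: [24, 24, 24]
  sd_scale: 1.0
n_subjects: 4
sex_ratio: 0.58
n_studies: 1
snr_target: 5.0
qc_threshold: 3.0
inversion:
  max_global: 4
template_space: false
erode_rois: true
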