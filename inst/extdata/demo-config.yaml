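# Demo pipeline configuration: two-group biodistribution study under the
# ex vivo acquisition protocol, with LOD calibration for both probes.
seed: 1
acq:
  n_averages: 512
  recycle_delay: 1.5
design:
  n_mice_per_group: 15
  timepoints_d: [2, 7, 14]
  misinjection_fraction: 0.05
  death_rate_per_day: 0.05
  division_interval_h: 36
  homing_jitter_cv: 0.25
lod:
  atom_counts: [3.16e15, 1.0e16, 3.16e16, 1.0e17, 3.16e17, 1.0e18, 3.16e18, 1.0e19]
  sensitivity:
    5mm: 1.4286
    10mm: 0.25
  threshold: 2
  n_averages: 128
  recycle_delay: 10
report:
  alpha: 0.05
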