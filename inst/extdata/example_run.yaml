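# Example run configuration for occupet::run_pipeline() /
# scripts/run_pipeline.R: a 4-subject crossover simulation with the
# default 33-frame schedule and striatal region set.
mode: simulate
seed: 7
voxel: false
cohort:
  n_subjects: 4
  recenter: false
  noise_scale: 0.1
  conditions:
    MP+LPS:
      mean: 17.1
      sd: 3.6
    MP+PBO:
      mean: 8.8
      sd: 3.6
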