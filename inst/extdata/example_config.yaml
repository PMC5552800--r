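# Example brightseg pipeline configuration. Any field omitted here keeps
# the package default (see default_pipeline_config()).
rng_seed: 1
mode: timelapse
n_sites: 9
heldout_site: 9
output_dir: brightseg_run

scene:
  width: 256
  height: 256
  n_cells: 15
  min_center_distance: 40
  noise_sd: 0.01

training:
  total_iterations: 2000

segmentation:
  dilation_size: 9
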