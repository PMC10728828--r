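# Demo audit configuration. All tables default to the packaged synthetic
# fixtures; point the *_csv entries at your own files for a real audit.
seed: 1
out_dir: null            # set by run_audit(); null means tempdir()
tile_edge_px: 512
cohort_csv: null         # null: generate a synthetic cohort
cohort:
  n_prostate_cases: 5
  n_breast_cases: 8
  target_correlation: 0.58
calibration_csv: null    # null: packaged models_synthetic.csv
region_csv: null         # null: packaged regions_synthetic.csv
driver_csv: null         # null: packaged driver_anchors_synthetic.csv
device_name: quadro_6000
scenarios: [one_task, two_task, seven_task, multitask]
input_modes: [wsi, tissue, roi]
size_classes: [small, medium, large]
extrapolation_scenario: multitask
extrapolation_mode: tissue
projection_years: [2023, 2052]
n_boot: 500
noise_sd: 0.02
scanner:
  n_slides: 237179
  power_w: 580
  minutes_per_slide: 1
  intensity_kg_per_kwh: 0.4
survey_cases_germany: 17550000
constants: {}
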