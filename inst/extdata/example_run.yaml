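# Example pipeline configuration: simulate a small two-group cohort and
# analyse it end to end. Run from anywhere:
#   Rscript inst/scripts/run_pipeline.R --config inst/extdata/example_run.yaml
output_dir: imcniche_example_output
seed: 7
params:
  median_window: 3
  q: 99
  k_expr: 15
  k_spatial: 20
  k_cn: 4
  n_perm: 100
  alpha: 0.05
simulate:
  nSamplesPerGroup: 1
  roisPerSample: 1
  roiWidth: 200
  roiHeight: 200
  meanCellsPerRoi: 200
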