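# End-to-end demo: small phantom with a nested lesion, plus a study-sized
# cohort. Run with:
#   Rscript inst/scripts/alps-glymph.R --config inst/extdata/demo_config.yaml --out demo_run
phantom:
  grid: [48, 48, 16]
  S0: 500
  noise_sigma: 0          # set to 10 for 2% Rician noise at S0 = 500
  lesion:
    hematoma: {center: [36, 36, 8], semiaxes: [3, 3, 2]}
    edema:    {center: [36, 36, 8], semiaxes: [5, 5, 4]}
lesion_side: right
cohort:
  n_sich: 55
  n_hc: 97
seeds:
  dwi: 11
  cohort: 12
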