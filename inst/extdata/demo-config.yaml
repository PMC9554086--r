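# Demo pipeline configuration: simulate a small CD-vs-control study and run
# the full discovery pipeline on it.
seed: 42
cohort_a: CD
cohort_b: HC
threshold: 0.025
motif_threshold: 0.7
label: CAIT
simulate:
  n_per_cohort:
    CD: 80
    HC: 80
  clones_per_repertoire: 500
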