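# Desk-scale experiment: two scenarios, FedAvg + FedProx, one schedule.
# Run with:
#   Rscript inst/scripts/fedus-experiment.R --config inst/extdata/experiment-tiny.yaml --out results/
profile: tiny
seed: 1
trials: 2
n_test_per_site: 10
images_per_patient: 4
algorithms:
  - fedavg
  - fedprox
epoch_schedules:
  - [1, 15]
scenarios:
  - id: source_based
    strategy: source_based
  - id: one_class_per_site
    strategy: quantity_class
    classes_per_site: 1
imbalance_grid:
  s0_fractions: [0.3, 0.5]
  alphas: [0.0, 0.5, 1.0]
  total_patients: 84
  n_sites: 2
  local_epochs: 1
  rounds: 10
train:
  arch: tiny
  batch_size: 32
  learning_rate: 0.001
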