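# Example pipeline configuration: synthetic corpus, PV-DM weak labeling,
# SVM training and gold-set evaluation.
#   Rscript inst/cli/amrtriage.R run --config inst/extdata/example_config.yaml
output_dir: results/example_run
method: pvdm
seed: 1
gold_subset_n: 30
embedding:
  vector_size: 300
  epochs: 30
svm:
  folds: 5
synthetic:
  n_relevant: 50
  n_irrelevant: 50
  lexicon_size: 50
  background_vocab_size: 500
  enrichment: 0.3
  background_rate: 0.05
  doc_length_mean: 120
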