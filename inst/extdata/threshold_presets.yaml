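# Published average decision thresholds (5-fold CV) for each scorer and
# dataset; outer limits are always -1 and +1.
- model: mlp
  dataset: students
  t_pos_neu: 0.49
  t_neu_neg: 0.22
- model: mlp
  dataset: staff
  t_pos_neu: 0.52
  t_neu_neg: 0.38
- model: svm
  dataset: students
  t_pos_neu: 0.41
  t_neu_neg: 0.24
- model: svm
  dataset: staff
  t_pos_neu: 0.42
  t_neu_neg: 0.26
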