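series,n_sarcoma,n_controls,sensitivity_pct,specificity_pct,reported_accuracy_pct
training,21,34,81,88,85
evaluation,19,33,84,94,90
validation,17,36,88,86,87
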