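# Column-name and value mapping for example_trials.csv; adapt this file to
# whatever headers a deposited archive uses.
columns:
  individual_id: cricket
  group: condition
  sex: sx
  trial_index: attempt
  emerged: left_tube
  latency_s: seconds
group_labels:
  clean: virus_free
  addv: infected
sex_labels:
  M: male
  F: female
sep: ","
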