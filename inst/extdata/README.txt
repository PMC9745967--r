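published_quant_table.csv
  Transcription of the published HPLC quantification of degradation
  products (micrograms and nanomoles, mean and sd of n = 3) for three
  reactions: transglucanase-pretreated LAM5 alone ("pretreated"), LAM5
  digested with the exo-glucanase ("LAM5_G9376"), and pretreated LAM5
  digested with the exo-glucanase ("pretreated_G9376"). The starting
  LAM5 amount in every reaction was 10.23 micrograms. These measured
  values serve as inputs to the accounting layer (difference formulas,
  percent reduction); they are data, not package output.
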