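{"TOY":{"class":["II"],"n_exons":[1],"exon_numbers":[2],"pbs_exons":[2]}}
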