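>TOY*01
CCTGA--ACGTACTGACC
>TOY*02
CCTGATTACGTACTGACC
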