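>TOY*01
--ACGTAC
>TOY*02
TTACGTAC
>TOY*03
--ACGAAC
>TOY*04
--ACGA-C
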