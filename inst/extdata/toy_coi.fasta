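>h1
ACGTACGTAC
>h2
ACGTACGTAT
>h3
ACGAACGTAT
>h4
TCGAACGTAT
>h5
ACGTACGGAC
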