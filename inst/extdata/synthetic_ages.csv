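label,age
angiosperms,140
core1,110
urtmor,65
mono,120
Rubiaceae,78
Annonaceae,82
Lauraceae,96
Moraceae,40
Urticaceae,38
Orchidaceae,76
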