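(((g01:20,g02:20,g03:20)Rubiaceae:40,(g04:25,g05:25)Annonaceae:35)core1:30,((g06:30,g07:30)Lauraceae:35,((g08:15,g09:15)Moraceae:25,(g10:18,g11:18)Urticaceae:22)urtmor:25):25,((g12:28,g13:28)Orchidaceae:40,g14:68)mono:22)angiosperms;
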