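"outcome","k","SMD","OS","TS","Nfs","n","threshold","robust"
"FI",6,-0.00655045483878465,0.940253614009291,0.05,0,6,40,FALSE
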