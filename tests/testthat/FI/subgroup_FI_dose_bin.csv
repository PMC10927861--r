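"level","k","estimate","ci_low","ci_high","p","I2","p_Q","tau2","Q"
"LOW",4,0.326409407206574,-0.203105482570885,0.855924296984032,0.226977028728592,10.4907949348294,0.340523765792299,0.0308276422204664,3.35161059448102
"MID",1,-0.80540859771221,-1.71677514901502,0.105957953590597,0.0832569622775317,NA,NA,NA,NA
"HIGH",1,-0.296207168106571,-1.10073491670205,0.508320580488908,0.470534203036432,NA,NA,NA,NA
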