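"level","k","estimate","ci_low","ci_high","p","I2","p_Q","tau2","Q"
"A. niger",2,0.509802650356005,-0.198478370302343,1.21808367101435,0.158323596235339,0,0.386437807780638,0,0.750121367639919
"A. niger + C. utilis",2,-0.118462743822555,-1.45888525315065,1.22195976550554,0.862481597113205,77.3307208478733,0.0357025390379797,0.723398932468895,4.41125627899018
"B. subtilis + Lactobacillus + Saccharomycetes",1,-0.296207168106571,-1.10073491670205,0.508320580488908,0.470534203036432,NA,NA,NA,NA
"T. harzianum",1,-0.519476868815403,-1.66998965506129,0.631035917430486,0.376179068818762,NA,NA,NA,NA
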