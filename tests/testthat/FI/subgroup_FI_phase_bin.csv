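"level","k","estimate","ci_low","ci_high","p","I2","p_Q","tau2","Q"
"starter",2,0.509802650356005,-0.198478370302343,1.21808367101435,0.158323596235339,0,0.386437807780638,0,0.750121367639919
"finisher",3,-0.232411833953269,-1.10643149967245,0.641607831765911,0.602243573079326,58.2188635013936,0.0913164253675301,0.346400998737315,4.78684920422572
"overall",1,-0.296207168106571,-1.10073491670205,0.508320580488908,0.470534203036432,NA,NA,NA,NA
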