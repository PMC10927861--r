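"level","k","estimate","ci_low","ci_high","p","I2","p_Q","tau2","Q"
"G. biloba",4,0.185539597722258,-0.528714007048736,0.899793202493251,0.610658169335826,55.7209650375564,0.0794182109965476,0.295645844681354,6.7752154096053
"M. alba",1,-0.296207168106571,-1.10073491670205,0.508320580488908,0.470534203036432,NA,NA,NA,NA
"S. androgynus",1,-0.519476868815403,-1.66998965506129,0.631035917430486,0.376179068818762,NA,NA,NA,NA
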