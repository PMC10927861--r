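"outcome","moderator","k","SMD","QM","p","I2_resid","R2"
"FI","strain",6,-0.00655045483878465,0.869510850506897,0.647422991030168,55.7209650375564,0
"FI","leaf_type",6,-0.00655045483878465,0.869510850506898,0.647422991030168,55.7209650375564,0
"FI","microbes",6,-0.00655045483878465,1.43312950180654,0.697787695823395,61.2506556014979,0
"FI","dose_bin",6,-0.00655045483878465,4.52235853109013,0.104227500353369,10.4907949348294,81.4721207506977
"FI","phase_bin",6,-0.00655045483878465,1.67980223186669,0.431753214831968,45.8187476154642,0
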