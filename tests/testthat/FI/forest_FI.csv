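"label","g","ci_low","ci_high","weight_pct"
"fix-01",0.835263906311566,-0.186556237180661,1.85708404980379,15.3116381773513
"fix-02",0.208815976577892,-0.773833089189277,1.19146504234506,16.0608010090903
"fix-03",0.562408097563378,-0.33127438252434,1.4560905776511,17.925445855294
"fix-04",-0.80540859771221,-1.71677514901502,0.105957953590597,17.5361340834565
"fix-09",-0.296207168106571,-1.10073491670205,0.508320580488908,20.0351462584279
"fix-10",-0.519476868815403,-1.66998965506129,0.631035917430486,13.1308346163799
"random-effects summary",-0.00655045483878465,-0.514228956884404,0.501128047206835,100
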