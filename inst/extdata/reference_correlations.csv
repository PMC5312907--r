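"","SRW09","DipoleZ","piPC05","Ram","X0Av","ATS6m","LogC_cal"
"SRW09",1,-0.004,-0.002,0.567,0.053,0.427,0.706
"DipoleZ",-0.004,1,0.009,0.068,-0.112,0.118,0.377
"piPC05",-0.002,0.009,1,0.631,-0.275,0.532,-0.037
"Ram",0.567,0.068,0.631,1,0.075,0.545,0.53
"X0Av",0.053,-0.112,-0.275,0.075,1,0.042,0.159
"ATS6m",0.427,0.118,0.532,0.545,0.042,1,0.276
"LogC_cal",0.706,0.377,-0.037,0.53,0.159,0.276,1
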