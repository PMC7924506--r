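"pressure","env","sensitivity"
"pressure01","env01",0.0911
"pressure02","env01",1.3625
"pressure01","env02",2.3829
"pressure02","env02",1.4138
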