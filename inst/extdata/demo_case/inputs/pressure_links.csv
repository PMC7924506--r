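"use","pressure","weight","distance_m"
"use01","pressure01",0.8527,1000
"use01","pressure02",0.26,1000
"use02","pressure02",0.523,2000
"use02","pressure01",0.5569,1000
"use03","pressure01",0.5009,1000
"use03","pressure02",0.7705,2000
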