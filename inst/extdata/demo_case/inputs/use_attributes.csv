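"use","vertical_domain","spatial_domain","temporal_domain","mobility"
"use01","surface;water_column","local","year_round","fixed"
"use02","surface;seabed","local","seasonal","fixed"
"use03","seabed;surface;water_column","local","seasonal","fixed"
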