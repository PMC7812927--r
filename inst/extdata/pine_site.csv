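key,value
pH,3.5
pct_sand,93
fClay,0.03
pct_SOM,3
D_b,1.4
layer_thickness,0.3
annual_litterfall,400
annual_rootlitter,740
annual_myc_alloc,197
exudation_daily,0.1
root_pool,400
fine_root_growth,210
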