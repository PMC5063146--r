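# Synthetic digitization of mean lifespan (egg-origin) vs constant
# temperature for D. melanogaster, constructed from classic published
# laboratory values; lifespan decreases monotonically with temperature
# and always exceeds the development time at the same temperature.
temperature_C,days
12,180
15,140
18,103
21,78
25,52
27,40
30,25
32,17
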