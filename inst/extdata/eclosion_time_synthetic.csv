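# Synthetic digitization of egg-to-adult development time vs constant
# rearing temperature for D. melanogaster, constructed from classic
# published laboratory values; fastest development at 25 C.
temperature_C,days
12,50
14,35
16,25
18,19
20,14.5
22,12
25,9.5
27,10
28,10.5
30,12
32,15.5
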