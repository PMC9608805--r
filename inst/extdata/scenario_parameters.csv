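scenario,gdp_change_rate_pct,pop_change_rate_pct
high,13.66,0.52
medium,10.40,0.35
low,8.00,0.22
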