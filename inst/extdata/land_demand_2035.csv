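scenario,grassland,cultivated,construction,forest,water,garden,other
low,0.50,437.30,191.58,896.66,90.05,50.44,20.18
medium,0.32,431.04,212.76,877.62,83.96,56.74,24.26
high,0.01,418.40,256.64,837.64,71.51,69.83,32.68
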