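indicator,year,historical,simulated
total_population,2011,587107,584262
total_population,2012,588358,584438
total_population,2013,589146,584613
total_population,2014,583983,584788
total_population,2015,583662,584964
total_population,2016,584953,585139
total_population,2017,585723,585315
total_population,2018,583969,585490
construction,2011,161.04,158.90
construction,2012,159.73,159.52
construction,2013,158.94,160.22
construction,2014,161.62,161.03
construction,2015,161.92,160.46
construction,2016,162.37,161.10
construction,2017,162.37,161.60
construction,2018,162.05,162.36
cultivated,2011,437.22,438.49
cultivated,2012,438.13,438.33
cultivated,2013,438.84,438.11
cultivated,2014,436.77,437.81
cultivated,2015,437.56,439.46
cultivated,2016,438.28,439.59
cultivated,2017,438.28,439.95
cultivated,2018,442.64,440.11
forest,2011,929.30,932.76
forest,2012,929.56,932.13
forest,2013,930.15,931.39
forest,2014,929.12,930.57
forest,2015,928.42,930.20
forest,2016,927.29,929.38
forest,2017,927.29,928.43
forest,2018,923.36,927.42
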