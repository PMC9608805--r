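service,cultivated,grassland,forest,water,garden,other,construction
gas_regulation,1851.52,3234.95,4514.37,1601.87,2933.30,135.22,0
climate_regulation,967.37,8560.66,13522.31,4764.02,8799.91,104.02,0
water_conservation,3110.13,6272.27,9860.89,212695.60,6969.19,249.64,0
waste_treatment,280.85,2829.28,4015.09,11545.98,2662.86,426.47,0
soil_formation_protection,1081.79,3942.27,5512.94,1934.73,3578.21,156.03,0
biodiversity_protection,353.66,3588.61,5013.66,5304.91,3266.16,145.62,0
food_production,2298.79,624.11,603.30,1664.28,395.27,10.40,0
raw_material,509.69,925.76,1373.03,478.48,894.55,31.21,0
entertainment,156.03,1581.07,2205.18,3931.87,1435.45,62.41,0
total,10609.82,31559.00,46620.78,243921.74,30934.89,1321.03,0
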