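region,financial_year,cattle_sold,herd_size,area_ha,stocking_rate,n_farms
NSW,2015,257,383,1672,0.24,598
NSW,2016,222,282,1705,0.18,605
NSW,2017,159,417,1208,0.33,349
NSW,2018,228,301,1373,0.24,414
NSW,mean,217,346,1490,0.25,492
Victoria,2015,145,320,408,0.80,3029
Victoria,2016,235,489,740,0.66,1101
Victoria,2017,138,320,447,0.72,2076
Victoria,2018,188,511,622,0.80,1350
Victoria,mean,177,410,554,0.75,1889
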