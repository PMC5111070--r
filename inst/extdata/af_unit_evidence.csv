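# Atlantic Forest priority-area evidence table (one row per candidate
# conservation unit). pop_* empty = unit not surveyed with population
# models. good_area_km2 is NOT printed in the source table: for the 12
# named units it is backfilled with the AJO area as a proxy; for the
# aggregate small-fragments row that proxy would contradict the row's
# definition (member fragments each hold < 230 km2 of good habitat), so a
# synthetic 100 km2 is used there. Both values are documented in the
# package vignette.
name,both_sexes,total_area_km2,ajo_km2,apjo_km2,good_area_km2,pct_surveyed,pop_point,pop_low,pop_high
Green Corridor,1,14535,13430,1105,13430,62,52,38,64
Upper Parana-Paranapanema,1,6724,5343,1380,5343,49,47,26,67
Serra do Mar,1,13547,7315,6232,7315,32,14,6,24
Mbaracayu,1,4086,2643,1443,2643,48,12,8,18
Linhares-Sooretama,1,503,503,0,503,79,10,9,14
Rio Doce,1,1407,1113,294,1113,0,,,
Serra do Mar Norte,1,3915,1006,2908,1006,3,,,
San Rafael,0,2941,1958,983,1958,0,,,
Itaipu,0,2258,1460,798,1460,0,,,
Serra dos Orgaos,0,1578,827,751,827,47,,,
Itatiaia,0,1336,1000,336,1000,0,,,
Campos do Jordao,0,539,536,3,536,0,,,
Small fragments,0,877,690,187,100,0,,,
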