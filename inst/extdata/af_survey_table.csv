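# Camera-trap survey table: stations, effort (camera-trap days), record
# rate per 100 trap days, individuals by sex/age (f female, m male,
# u undetermined adult, c cub), and the published density estimate with
# its 95% interval (NA = not estimated due to scarcity of records).
survey,stations,trap_days,rate_per100,n_f,n_m,n_u,n_c,density,ci_low,ci_high
Morombi PR I,5,918,0.11,0,0,1,0,,,
Morombi PR II,10,930,0.75,0,1,3,0,,,
Mbaracayu,25,1844,2.87,3,2,3,0,1.29,1.29,2.8
Urugua-i,53,2611,0.11,0,1,0,0,,,
PN Iguazu,46,2942,0.58,3,2,1,0,,,
Yaboti,60,2676,0.15,0,1,0,0,,,
Iguazu-San Jorge,49,2287,1.92,6,4,1,2,1.2,0.56,1.89
Iguazu-Urugua-i,47,2327,2.15,8,8,0,0,0.89,0.58,1.24
PN do Iguacu I,36,3240,0.21,2,0,1,0,,,
Green Corridor I,80,5038,1.47,10,7,2,2,0.91,0.61,1.22
PN do Iguacu II,34,3060,0.75,2,2,0,0,,,
Green Corridor II,122,5297,3.51,18,12,1,10,1.07,0.8,1.33
Morro do Diabo,36,1440,5.41,6,4,0,0,2.39,2.31,2.57
Ivinhema,13,1495,2.07,8,3,1,0,1.66,0.76,2.55
Vale NR I,30,3032,2.74,4,3,1,0,2.42,2.01,3.26
Vale NR II,10,3468,0.09,3,0,0,0,,,
Vale NR III,10,3034,0.07,0,1,1,0,,,
Vale NR IV,8,1033,3.1,1,3,0,0,,,
Vale NR V,30,1440,1.67,0,2,0,0,,,
Carlos Botelho,16,2170,0.23,1,0,3,0,,,
Intervales,14,1497,1.94,2,2,0,0,,,
Intervales-PETAR,24,2712,1.25,3,3,2,0,0.66,0.29,1.17
Jureia-Itatins,21,2483,0,0,0,0,0,,,
Ilha do Cardoso,8,744,0,0,0,0,0,,,
Serra da Bocaina,26,3054,0,0,0,0,0,,,
Santa Virginia,26,2512,0,0,0,0,0,,,
Serra dos Orgaos I,18,1354,0,0,0,0,0,,,
Serra dos Orgaos II,20,6624,0,0,0,0,0,,,
Serra dos Orgaos III,44,4597,0,0,0,0,0,,,
Serra dos Orgaos IV,48,4788,0,0,0,0,0,,,
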