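name: gaarlandia
areas: Andes-North Brazil-Atlantic Brazil-Boreal Brazil-South Caribbean Mesoamerica Mexican-Transition-Zone Pacific Nearctic Asia
bounds: 0 3 20 30 40 120
stratum: 1
1.00 0.25 0.50 0.50 0.25 0.25 0.25 0.50 0.25 0.25
0.25 1.00 0.25 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.25 1.00 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.50 0.50 1.00 0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 1.00 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 1.00 0.50 0.50 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.50 1.00 0.25 0.50 0.25
0.50 0.25 0.25 0.25 0.25 0.50 0.25 1.00 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.50 0.25 1.00 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 1.00
stratum: 2
1.00 0.25 0.50 0.50 0.25 0.25 0.25 0.50 0.25 0.25
0.25 1.00 0.25 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.25 1.00 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.50 0.50 1.00 0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 1.00 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 1.00 0.50 0.50 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.50 1.00 0.25 0.50 0.25
0.50 0.25 0.25 0.25 0.25 0.50 0.25 1.00 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.50 0.25 1.00 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 1.00
stratum: 3
1.00 0.25 0.50 0.50 0.25 0.25 0.25 0.50 0.25 0.25
0.25 1.00 0.25 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.25 1.00 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.50 0.50 1.00 0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 1.00 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 1.00 0.50 0.01 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.50 1.00 0.25 0.50 0.25
0.50 0.25 0.25 0.25 0.25 0.01 0.25 1.00 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.50 0.25 1.00 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 1.00
stratum: 4
1.00 0.25 0.50 0.50 0.50 0.25 0.25 0.50 0.25 0.25
0.25 1.00 0.25 0.50 0.50 0.25 0.25 0.25 0.25 0.25
0.50 0.25 1.00 0.50 0.50 0.25 0.25 0.25 0.25 0.25
0.50 0.50 0.50 1.00 0.50 0.25 0.25 0.25 0.25 0.25
0.5 0.5 0.5 0.5 1.0 0.5 0.5 0.5 0.5 0.5
0.25 0.25 0.25 0.25 0.50 1.00 0.50 0.01 0.25 0.25
0.25 0.25 0.25 0.25 0.50 0.50 1.00 0.25 0.50 0.25
0.50 0.25 0.25 0.25 0.50 0.01 0.25 1.00 0.25 0.25
0.25 0.25 0.25 0.25 0.50 0.25 0.50 0.25 1.00 0.25
0.25 0.25 0.25 0.25 0.50 0.25 0.25 0.25 0.25 1.00
stratum: 5
1.00 0.25 0.50 0.50 0.25 0.25 0.25 0.50 0.25 0.25
0.25 1.00 0.25 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.25 1.00 0.50 0.25 0.25 0.25 0.25 0.25 0.25
0.50 0.50 0.50 1.00 0.25 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 1.00 0.25 0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25 0.25 1.00 0.50 0.01 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.50 1.00 0.25 0.50 0.25
0.50 0.25 0.25 0.25 0.25 0.01 0.25 1.00 0.25 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.50 0.25 1.00 0.25
0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 0.25 1.00
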