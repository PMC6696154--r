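frequency_hz,modulus_ohm,phase_rad
250000,235.55872,-0.0740422
125000,242.33682,-0.0852266
62500,251.06561,-0.1040394
31250,262.43457,-0.1302557
15625,277.09086,-0.1660522
7812.5,295.96917,-0.2183331
3906.25,321.75482,-0.3006170
1953.125,362.5306,-0.4326722
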