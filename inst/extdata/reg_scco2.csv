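T_K,P_bar,rho_kg_m3,y2,S_gL,sd,U
308,120,769,0.00000125,0.0106,0.00000005,0.00000058
308,150,817,0.00000173,0.0155,0.00000007,0.00000078
308,180,849,0.00000192,0.0180,0.00000002,0.00000086
308,210,875,0.00000235,0.0226,0.00000008,0.00000104
308,240,896,0.00000297,0.0292,0.00000011,0.00000131
308,270,914,0.00000313,0.0315,0.00000010,0.00000138
318,120,661,0.00000101,0.0072,0.00000003,0.00000046
318,150,744,0.00000121,0.0098,0.00000004,0.00000054
318,180,791,0.00000143,0.0124,0.00000002,0.00000064
318,210,824,0.00000317,0.0287,0.00000005,0.00000141
318,240,851,0.00000342,0.0319,0.00000002,0.00000151
318,270,872,0.00000389,0.0372,0.00000003,0.00000171
328,120,509,0.00000064,0.0036,0.00000002,0.00000030
328,150,656,0.00000098,0.0070,0.00000004,0.00000044
328,180,725,0.00000126,0.0100,0.00000006,0.00000056
328,210,769,0.00000392,0.0331,0.00000003,0.00000174
328,240,802,0.00000421,0.0371,0.00000007,0.00000186
328,270,829,0.00000431,0.0392,0.00000006,0.00000191
338,120,388,0.00000031,0.0013,0.00000001,0.00000014
338,150,557,0.00000062,0.0037,0.00000003,0.00000028
338,180,652,0.00000102,0.0072,0.00000001,0.00000044
338,210,710,0.00000443,0.0346,0.00000012,0.00000197
338,240,751,0.00000497,0.0410,0.00000009,0.00000220
338,270,783,0.00000644,0.0553,0.00000006,0.00000284
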