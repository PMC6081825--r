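# Ruifrok-Johnston H&E optical-density vectors (row-major 3x2: rows R,G,B; cols H,E)
0.650 0.070
0.700 0.990
0.290 0.110
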