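subreach_id,length_m,depth_cm,complexity
1,42,21.0,40.0
2,49,23.7,46.1
3,58,23.7,40.8
4,47,21.7,28.8
5,38,20.1,36.8
6,58,21.9,32.5
7,48,21.1,24.2
8,56,25.8,31.5
9,48,16.6,23.1
10,48,19.1,19.2
11,56,17.3,39.1
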