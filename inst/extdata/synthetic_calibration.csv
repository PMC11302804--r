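"dose_Gy","mean_green_response"
0,40000
0.25,37454.55
0.5,35333.33
0.75,33538.46
1,32000
1.5,29500
2,27555.56
3,24727.27
4,22769.23
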