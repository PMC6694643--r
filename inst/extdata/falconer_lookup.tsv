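q	x	a
0.2643	0.681	1.278
0.4264	0.251	0.962
0.1502	1.062	1.575
0.2010	0.845	1.406
0.1109	1.301	1.761
0.1569	1.089	1.623
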