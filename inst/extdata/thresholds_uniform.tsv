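#provenance	builtin
#convention	raw-deflate/level=1/windowBits=-15/memLevel=8
read_length	threshold	sensitivity	specificity	background	seed
75	0.466666666666667	1	1	uniform/background	101
100	0.47	1	1	uniform/background	101
124	0.443548387096774	1	1	uniform/background	101
125	0.448	1	1	uniform/background	101
150	0.44	0.99995	0.99995	uniform/background	101
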