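# unit test fixture: axis-aligned cube, edge length 2
v 0 0 0
v 2 0 0
v 0 2 0
v 2 2 0
v 0 0 2
v 2 0 2
v 0 2 2
v 2 2 2
f 1 2 4
f 1 4 3
f 5 7 8
f 5 8 6
f 1 5 6
f 1 6 2
f 3 4 8
f 3 8 7
f 1 3 7
f 1 7 5
f 2 6 8
f 2 8 4
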