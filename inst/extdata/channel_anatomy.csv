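channel,scenario,hemisphere,mni_x,mni_y,mni_z,anatomy
1,japanese,Left,-50,22,38,Left middle frontal gyrus (BA 44)
6,japanese,Left,-61,7,28,Left precentral gyrus (BA 6)
22,japanese,Left,-61,-62,-8,Left inferior temporal gyrus (BA 37)
16,japanese,Right,71,-25,4,Right superior temporal gyrus (BA 21)
2,english,Left,-60,-7,43,Left postcentral gyrus (BA 4)
9,english,Left,-52,-72,35,Left angular gyrus (BA 39)
15,english,Left,-62,2,1,Left superior temporal gyrus (BA 48)
17,english,Left,-67,-50,6,Left middle temporal gyrus (BA 21)
19,english,Right,58,10,-18,Right middle temporal gyrus (BA 21)
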