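# rows=10 cols=6
-0.935061,-2.14703,0.708727,-1.764293,-0.405477,-1.671329
-0.530719,0.471381,0.106049,-0.424196,-0.800384,1.373484
-0.006539,1.041145,-0.091643,0.340746,0.43754,0.145586
0.636192,-1.237966,-0.496071,0.015587,0.989159,0.78095
-0.158795,-0.185278,-1.251316,-0.564957,0.015151,-0.920834
0.724716,-0.946248,1.15083,-0.500314,-0.735357,0.162188
-0.752017,0.662776,0.799343,-0.535446,0.539691,-0.375066
1.320101,-0.265749,-0.283496,0.804696,0.958063,1.944776
2.108542,-0.486116,-0.534427,-0.822821,0.171326,0.779549
0.369284,0.484026,0.036646,-1.0066,0.520233,1.1642
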