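compound,label,A,B
a1,1,9.0,9.1
a2,1,8.5,8.0
a3,1,7.8,6.5
a4,1,6.8,6.0
a5,1,6.6,7.9
a6,1,6.4,7.7
a7,1,6.2,5.9
a8,1,6.0,5.7
i1,0,8.0,8.2
i2,0,7.5,5.0
i3,0,5.8,7.6
i4,0,5.6,5.4
i5,0,5.4,5.2
i6,0,5.2,5.1
i7,0,5.0,4.9
i8,0,4.8,4.8
i9,0,4.6,4.7
i10,0,4.4,4.6
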