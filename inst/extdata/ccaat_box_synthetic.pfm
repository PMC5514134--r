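>SYN0001 CCAAT_box_synthetic
A [  3  2 88 95  2 10 ]
C [ 90 92  5  1  3 20 ]
G [  4  3  4  2  3 60 ]
T [  3  3  3  2 92 10 ]
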