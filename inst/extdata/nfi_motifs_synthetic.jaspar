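>NFI_full NFI-full-site-synthetic
A [  3  3  3  3 91 25 25 25  3  3  3  3 91 ]
C [  3  3  3 91  3 25 25 25  3  3 91 91  3 ]
G [  3 91 91  3  3 25 25 25  3 91  3  3  3 ]
T [ 91  3  3  3  3 25 25 25 91  3  3  3  3 ]
>NFI_half_T NFI-half-site-TGCCAA-synthetic
A [  3  3  3  3 91 91 ]
C [  3  3 91 91  3  3 ]
G [  3 91  3  3  3  3 ]
T [ 91  3  3  3  3  3 ]
>NFI_half NFI-half-site-GCCAA-synthetic
A [  3  3  3 91 91 ]
C [  3 91 91  3  3 ]
G [ 91  3  3  3  3 ]
T [  3  3  3  3  3 ]
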