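>FIXM01 ftf1
A [  5  5 85  5  5  5  5 85 85  5 ]
C [  5  5  5 85  5  5 85  5  5  5 ]
G [  5 85  5  5 85  5  5  5  5  5 ]
T [ 85  5  5  5  5 85  5  5  5 85 ]
>FIXM02 ftf2
A [  5  5 85 85  5  5  5  5  5  5 ]
C [ 85 85  5  5  5  5  5 85  5  5 ]
G [  5  5  5  5  5 85 85  5  5 85 ]
T [  5  5  5  5 85  5  5  5 85  5 ]
>FIXM03 ftf3
A [  5  5  5  5  5  5  5 85  5  5 ]
C [  5  5  5 85  5  5  5  5 85  5 ]
G [ 85 85 85  5 85 85 85  5  5  5 ]
T [  5  5  5  5  5  5  5  5  5 85 ]
>FIXM04 ftf4
A [ 85  5  5  5 85 85 85  5  5 85 ]
C [  5  5  5 85  5  5  5  5 85  5 ]
G [  5  5 85  5  5  5  5  5  5  5 ]
T [  5 85  5  5  5  5  5 85  5  5 ]
>FIXM05 ftf5
A [  5 85  5  5  5  5 85  5  5  5 ]
C [ 85  5 85  5  5  5  5 85  5  5 ]
G [  5  5  5 85  5 85  5  5  5  5 ]
T [  5  5  5  5 85  5  5  5 85 85 ]
>FIXM06 ftf6
A [  5  5 85  5  5 85  5  5  5  5 ]
C [  5  5  5  5 85  5  5  5 85  5 ]
G [  5  5  5 85  5  5  5 85  5 85 ]
T [ 85 85  5  5  5  5 85  5  5  5 ]
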