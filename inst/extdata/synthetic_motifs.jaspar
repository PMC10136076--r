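>SYNM01 FIBTF1
A [ 98 2 2 0 2 0 98 0 0 98 2 0 0 0 0 2 0 0 2 0 0 2 2 98 ]
C [ 0 98 0 2 0 0 2 98 0 2 98 0 0 0 98 98 98 0 0 98 98 98 0 0 ]
G [ 0 0 0 0 98 98 0 0 98 0 0 98 2 98 0 0 2 98 98 0 0 0 0 2 ]
T [ 2 0 98 98 0 2 0 2 2 0 0 2 98 2 2 0 0 2 0 2 2 0 98 0 ]
>SYNM02 DECTF2
A [ 0 98 98 98 98 98 0 0 98 0 2 98 2 98 0 0 0 2 ]
C [ 2 0 0 0 0 0 2 2 0 0 0 0 0 0 0 0 2 0 ]
G [ 98 2 2 0 0 0 98 98 0 98 98 0 98 2 2 2 0 0 ]
T [ 0 0 0 2 2 2 0 0 2 2 0 2 0 0 98 98 98 98 ]
>SYNM03 DECTF3
A [ 0 0 2 98 2 2 0 2 98 0 0 0 0 2 0 0 98 2 2 0 ]
C [ 0 98 98 0 0 0 2 0 0 0 2 2 98 0 0 0 0 0 0 2 ]
G [ 2 0 0 2 98 98 98 0 0 98 98 0 2 98 2 2 2 0 98 98 ]
T [ 98 2 0 0 0 0 0 98 2 2 0 98 0 0 98 98 0 98 0 0 ]
>SYNM04 DECTF4
A [ 0 98 2 2 0 98 98 0 2 98 2 98 0 98 2 98 2 2 2 0 0 2 ]
C [ 98 0 0 0 98 2 0 0 98 0 98 2 2 0 98 0 98 0 0 98 2 98 ]
G [ 0 0 0 98 0 0 2 2 0 0 0 0 98 0 0 0 0 98 98 2 98 0 ]
T [ 2 2 98 0 2 0 0 98 0 2 0 0 0 2 0 2 0 0 0 0 0 0 ]
>SYNM05 DECTF5
A [ 98 2 2 0 0 2 0 0 0 0 98 0 2 0 0 0 ]
C [ 2 98 0 0 0 98 0 98 98 98 2 0 0 0 0 2 ]
G [ 0 0 98 98 2 0 98 2 2 0 0 98 98 98 98 0 ]
T [ 0 0 0 2 98 0 2 0 0 2 0 2 0 2 2 98 ]
>SYNM06 EPITF6
A [ 0 2 2 2 98 0 0 0 0 2 2 2 2 98 98 0 2 2 0 0 2 98 0 0 ]
C [ 0 0 98 0 2 0 0 2 2 0 98 98 0 2 0 2 0 98 98 2 0 0 2 0 ]
G [ 2 98 0 98 0 2 2 0 98 0 0 0 98 0 0 98 0 0 0 98 0 2 98 98 ]
T [ 98 0 0 0 0 98 98 98 0 98 0 0 0 0 2 0 98 0 2 0 98 0 0 2 ]
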