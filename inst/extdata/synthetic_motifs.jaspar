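>SYNM01 synthetic-bZIP-like
A  [  2  1 94  2  1  2  2 94  2  1 ]
C  [  1  2  2 94  2  2 94  1  2 96 ]
G  [  2 95  2  1 95  1  2  2 94  2 ]
T  [ 95  2  2  3  2 95  2  3  2  1 ]
>SYNM02 synthetic-ETS-like
A  [  3 90  2  2  1  2 88  4 ]
C  [ 90  4  3  2  1  2  4  4 ]
G  [  4  3 92 93  2 94  4 88 ]
T  [  3  3  3  3 96  2  4  4 ]
>SYNM03 synthetic-bHLH-like
A  [  4  2 90  2  2  2  3 90  3  2 ]
C  [ 88  4  3 92  2  2 90  3  3  4 ]
G  [  4  4  4  3 93 92  3  4 90  2 ]
T  [  4 90  3  3  3  4  4  3  4 92 ]
>SYNM04 synthetic-homeobox-like
A  [ 88  3 90 90  3  2  3  2  4 ]
C  [  4  4  3  3  3  3 90  4  4 ]
G  [  4  3  3  3  2 91  3  4 88 ]
T  [  4 90  4  4 92  4  4 90  4 ]
>SYNM05 synthetic-zinc-finger-like
A  [  2  3  3 90  3  2  3  2  3  3  2  3 ]
C  [ 92  4 90  3  3 92  4  3 90  4  3 90 ]
G  [  3 90  4  4 91  3 90  4  4 90  3  4 ]
T  [  3  3  3  3  3  3  3 91  3  3 92  3 ]
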