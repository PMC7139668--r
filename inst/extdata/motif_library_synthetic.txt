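# Synthetic known-motif count-matrix library (JASPAR-style layout).
# Matrices are constructed from the canonical published consensus sequences
# of the estrogen-receptor co-factor motifs (estrogen response element,
# direct repeat 1, forkhead, GATA, AP-1, AP-2 gamma, CTCF core, nuclear
# receptor half-site); 100 observations per position, 85 on the consensus
# base, 25 each at degenerate positions. This file is a synthetic stand-in
# for database-derived matrices, intended for simulation and testing.

>ERE
A [ 5 5 5 5 85 25 25 25 5 5 85 5 5 ]
C [ 5 5 5 85 5 25 25 25 5 5 5 85 85 ]
G [ 85 85 5 5 5 25 25 25 5 85 5 5 5 ]
T [ 5 5 85 5 5 25 25 25 85 5 5 5 5 ]
>DR1
A [ 85 5 5 5 5 85 25 85 5 5 5 5 85 ]
C [ 5 5 5 5 85 5 25 5 5 5 5 85 5 ]
G [ 5 85 85 5 5 5 25 5 85 85 5 5 5 ]
T [ 5 5 5 85 5 5 25 5 5 5 85 5 5 ]
>FOXA1
A [ 5 5 5 5 5 85 5 ]
C [ 5 5 5 5 5 5 85 ]
G [ 5 85 5 5 5 5 5 ]
T [ 85 5 85 85 85 5 5 ]
>GATA3
A [ 85 5 85 5 85 85 5 85 ]
C [ 5 5 5 5 5 5 5 5 ]
G [ 5 85 5 5 5 5 85 5 ]
T [ 5 5 5 85 5 5 5 5 ]
>AP-1
A [ 5 5 85 5 5 5 85 ]
C [ 5 5 5 85 5 85 5 ]
G [ 5 85 5 5 5 5 5 ]
T [ 85 5 5 5 85 5 5 ]
>AP2G
A [ 5 5 5 5 5 85 5 5 5 ]
C [ 5 85 85 5 5 5 5 5 85 ]
G [ 85 5 5 5 85 5 85 85 5 ]
T [ 5 5 5 85 5 5 5 5 5 ]
>CTCF
A [ 5 5 85 5 5 85 5 5 5 5 5 5 5 5 5 ]
C [ 85 85 5 85 85 5 5 5 5 5 5 85 5 85 5 ]
G [ 5 5 5 5 5 5 85 85 85 85 85 5 85 5 5 ]
T [ 5 5 5 5 5 5 5 5 5 5 5 5 5 5 85 ]
>NR_half
A [ 85 5 5 5 5 85 ]
C [ 5 5 5 5 85 5 ]
G [ 5 85 85 5 5 5 ]
T [ 5 5 5 85 5 5 ]
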