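H SNEP660103
D Principal component III (Sneath, 1966)
R
A Sneath, P.H.A.
T Relations between chemical structure and biological activity in peptides
J J. Theor. Biol. 17, 157-195 (1966)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    -0.11   0.079  -0.136  -0.285  -0.184  -0.067  -0.246  -0.073    0.32   0.001
   -0.008   0.049  -0.041   0.438  -0.016  -0.153  -0.208   0.493   0.381  -0.155
//
H TAKK010101
D Side-chain contribution to protein stability (Takano-Yutani, 2001)
R
A Takano, K. and Yutani, K.
T A new scale for side-chain contribution to protein stability
J Protein Eng. 14, 525-528 (2001)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      9.8     7.3     3.6     4.9       3     2.4     4.4       0    11.9    17.2
       17    10.5    11.9      23      15     2.6     6.9    24.2    17.2    15.3
//
H KARP850101
D Flexibility parameter for no rigid neighbors (Karplus-Schulz, 1985)
R
A Karplus, P.A. and Schulz, G.E.
T Prediction of chain flexibility in proteins
J Naturwissenschaften 72, 212-213 (1985)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.041   1.038   1.117   1.033    0.96   1.165   1.094   1.142   0.982   1.002
    0.967   1.093   0.947    0.93   1.055   1.169   1.073   0.925   0.961   0.982
//
H SYNTH000001
D Synthetic complete test scale (not a real AAindex entry)
R
A None
T Synthetic fixture
J None
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.05     0.1    0.15     0.2    0.25     0.3    0.35     0.4    0.45     0.5
     0.55     0.6    0.65     0.7    0.75     0.8    0.85     0.9    0.95       1
//
H SYNTH000002
D Synthetic incomplete test scale with a missing value (not a real AAindex entry)
R
A None
T Synthetic fixture
J None
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
       NA       1       2       3       4       5       6       7       8       9
       10      11      12      13      14      15      16      17      18      19
//
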