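aa	score	bfactor_hbp_mean	bfactor_hbp_sd	bfactor_nonhbp_mean	bfactor_nonhbp_sd
A	558.8	29.14	21.42	30.85	20.2
C	494.9	29.1	23.3	26.61	16.31
D	574.3	32	23.58	34.04	20.96
E	494.6	32.62	23.35	35.51	20.95
F	705.3	29.41	22.9	28.15	18.41
G	604.3	32	24.25	30.6	20.17
H	615.6	28.38	22.1	30.67	19.56
I	518.3	30.53	22.29	29.01	17.89
K	568.3	32.47	22.93	35.76	21.87
L	570.1	31.11	23.27	29.04	18.19
M	599.6	29.96	22.34	30.2	19.06
N	468.7	31.88	23.42	32.66	20.79
P	601.3	30.6	23.23	32.66	20.87
Q	511.2	32.2	24.31	33.27	20.8
R	566.1	31.83	24.25	33.24	20.55
S	401.4	32.34	23.93	32.13	20.33
T	498.6	31.22	23.47	30.08	19.36
V	535.5	30.19	22.4	28.02	17.71
W	603.1	29.48	22.98	25.18	16.77
Y	541	29.73	22.51	26.99	17.72
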