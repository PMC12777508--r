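symbol	mass	abundance
H	1.00782503207	0.999885
H	2.01410177785	0.000115
C	12.0	0.9893
C	13.00335483507	0.0107
N	14.00307400443	0.99636
N	15.00010889888	0.00364
O	15.99491461957	0.99757
O	16.99913175650	0.00038
O	17.99915961286	0.00205
P	30.97376199842	1.0
K	38.96370648643	0.932581
K	39.96399817000	0.000117
K	40.96182525792	0.067302
Na	22.98976928200	1.0
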