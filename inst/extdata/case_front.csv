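solution,n_selected,patient_cost,hospital_cost
1,7,257313.27,1194297.59
2,9,255472.26,1194765.01
3,11,253492.38,1195964.90
4,13,250206.89,1198833.75
5,13,248451.44,1204843.01
6,14,247975.42,1212564.85
7,15,246969.38,1220250.66
8,15,246906.36,1228940.93
9,18,246631.62,1247665.54
10,16,246498.87,1248898.04
A,10,289989.81,1358774.19
B,10,292200.42,1370623.31
C,10,333162.04,1627151.88
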