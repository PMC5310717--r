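locus,group,Ar,Ho,He,P
D15,myotis,9.5,0.96,0.89,0.123
F19,myotis,7.2,0.75,0.79,0.025
G2-Mluc,myotis,9.7,0.79,0.87,0.025
G6-Mluc,myotis,6.1,0.74,0.77,0
G31-Mluc,myotis,6.6,0.83,0.81,0.086
B8-Mluc,myotis,10.4,0.76,0.90,0
C113,myotis,1.1,0.01,0.02,0.011
D15-Mluc,myotis,9.3,0.81,0.86,0.137
F19-Mluc,myotis,6.8,0.71,0.77,0.0128
G30-Mluc,myotis,8.7,0.73,0.87,0
H23-Mluc,myotis,8.8,0.86,0.88,0.611
D15,blythii,6.0,0.42,0.66,0.048
F19,blythii,7.0,0.83,0.82,0.490
G2-Mluc,blythii,8.0,0.92,0.81,0.891
G6-Mluc,blythii,6.0,0.50,0.71,0.095
G31-Mluc,blythii,6.0,0.83,0.82,0.110
B8-Mluc,blythii,10.0,0.83,0.89,0.062
C113,blythii,2.0,0.25,0.35,0.261
D15-Mluc,blythii,4.0,0.42,0.59,0.070
F19-Mluc,blythii,9.0,1.00,0.87,0.563
G30-Mluc,blythii,7.0,0.92,0.84,0.859
H23-Mluc,blythii,11.0,0.92,0.93,0.771
D15,hybrid,11.5,0.92,0.86,0.997
F19,hybrid,9.7,0.77,0.84,0.172
G2-Mluc,hybrid,9.8,0.77,0.92,0.047
G6-Mluc,hybrid,6.8,0.38,0.85,0.002
G31-Mluc,hybrid,6.0,0.69,0.83,0.086
B8-Mluc,hybrid,9.7,1.00,0.90,0.196
C113,hybrid,2.0,0.31,0.53,0.195
D15-Mluc,hybrid,8.8,0.85,0.84,0.235
F19-Mluc,hybrid,9.8,0.77,0.84,0.434
G30-Mluc,hybrid,9.8,0.77,0.91,0.003
H23-Mluc,hybrid,7.8,0.85,0.85,0.243
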