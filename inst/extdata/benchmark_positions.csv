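point_id,model,x,y,z
1,truth,0.20,2.00,3.00
2,truth,0.10,1.30,1.00
3,truth,0.50,0.60,0.40
4,truth,0.30,1.80,0.20
5,truth,1.20,1.20,1.30
6,truth,1.30,1.20,2.40
7,truth,1.50,1.50,0.10
8,truth,2.10,2.40,2.70
9,truth,3.00,2.10,2.10
10,truth,2.10,1.80,1.80
1,dtr,0.24,2.08,3.00
2,dtr,0.12,1.26,1.00
3,dtr,0.52,0.54,0.36
4,dtr,0.32,1.88,0.22
5,dtr,1.22,1.21,1.30
6,dtr,1.34,1.22,2.40
7,dtr,1.50,1.52,0.10
8,dtr,2.15,2.51,2.70
9,dtr,2.97,2.08,2.13
10,dtr,2.05,1.76,1.80
1,str,0.12,2.40,3.04
2,str,0.00,1.30,1.35
3,str,0.27,0.44,0.56
4,str,0.20,2.19,0.18
5,str,1.26,1.09,1.30
6,str,1.25,1.26,2.31
7,str,1.80,1.50,0.10
8,str,2.04,2.56,2.82
9,str,2.80,2.10,2.12
10,str,1.87,1.86,1.80
1,tcn,0.26,2.01,2.70
2,tcn,0.05,1.20,1.31
3,tcn,0.34,0.50,0.29
4,tcn,0.11,1.81,0.27
5,tcn,1.18,1.76,1.14
6,tcn,1.20,1.56,2.31
7,tcn,1.63,1.36,0.12
8,tcn,2.23,2.33,2.95
9,tcn,2.76,2.23,2.11
10,tcn,2.10,2.34,1.71
1,gru,0.11,1.80,2.06
2,gru,0.10,1.46,1.09
3,gru,0.56,0.44,0.08
4,gru,0.26,1.66,0.30
5,gru,1.30,1.66,1.87
6,gru,0.96,1.03,2.40
7,gru,1.34,1.31,0.21
8,gru,2.05,2.70,2.63
9,gru,3.00,2.10,1.70
10,gru,2.30,2.39,1.68
1,lstm,0.60,1.80,3.00
2,lstm,0.11,0.03,1.20
3,lstm,0.60,0.04,0.06
4,lstm,0.84,2.40,0.08
5,lstm,0.69,1.51,1.46
6,lstm,1.30,0.71,2.52
7,lstm,1.59,1.36,0.09
8,lstm,1.92,2.38,2.96
9,lstm,2.88,2.41,2.52
10,lstm,2.29,1.63,2.00
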