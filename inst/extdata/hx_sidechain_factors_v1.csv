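residue,form,acid_lambda,acid_rho,base_lambda,base_rho,pk
A,,0.00,0.00,0.00,0.00,
C,,-0.54,-0.46,0.62,0.55,
D,deprot,0.90,0.58,-0.30,-0.18,4.48
D,prot,-0.90,-0.12,0.69,0.60,4.48
E,deprot,-0.90,0.31,-0.51,-0.15,4.93
E,prot,-0.60,-0.27,0.24,0.39,4.93
F,,-0.52,-0.43,-0.24,0.06,
G,,-0.22,0.22,0.27,0.17,
H,deprot,0.00,0.00,-0.10,0.14,7.42
H,prot,-0.80,-0.51,0.80,0.83,7.42
I,,-0.91,-0.59,-0.73,-0.23,
K,,-0.56,-0.29,-0.04,0.12,
L,,-0.57,-0.13,-0.58,-0.21,
M,,-0.64,-0.28,-0.01,0.11,
N,,-0.58,-0.13,0.49,0.32,
P,,,-0.19,,-0.24,
Q,,-0.47,-0.27,0.06,0.20,
R,,-0.59,-0.32,0.08,0.22,
S,,-0.44,-0.39,0.37,0.30,
T,,-0.79,-0.47,-0.07,0.20,
V,,-0.74,-0.30,-0.70,-0.14,
W,,-0.40,-0.44,-0.41,-0.11,
Y,,-0.41,-0.37,-0.27,0.05,
cterm,deprot,0.05,,0.00,,4.00
cterm,prot,0.96,,-1.80,,4.00
nterm,,,-1.32,,1.62,
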