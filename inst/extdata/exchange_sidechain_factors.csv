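residue,term,side,direction,value
A,acid,left,both,0.00
A,acid,right,both,0.00
A,base,left,both,0.00
A,base,right,both,0.00
R,acid,left,both,-0.59
R,acid,right,both,-0.32
R,base,left,both,0.08
R,base,right,both,0.22
N,acid,left,both,-0.58
N,acid,right,both,-0.13
N,base,left,both,0.49
N,base,right,both,0.32
D_prot,acid,left,both,-0.90
D_prot,acid,right,both,-0.12
D_prot,base,left,both,0.69
D_prot,base,right,both,0.60
D_deprot,acid,left,both,0.90
D_deprot,acid,right,both,0.58
D_deprot,base,left,both,0.10
D_deprot,base,right,both,-0.18
C,acid,left,both,-0.54
C,acid,right,both,-0.46
C,base,left,both,0.62
C,base,right,both,0.55
E_prot,acid,left,both,-0.60
E_prot,acid,right,both,-0.27
E_prot,base,left,both,0.24
E_prot,base,right,both,0.39
E_deprot,acid,left,both,-0.90
E_deprot,acid,right,both,0.31
E_deprot,base,left,both,-0.11
E_deprot,base,right,both,-0.15
G,acid,left,both,-0.22
G,acid,right,both,0.22
G,base,left,both,0.27
G,base,right,both,0.17
H_prot,acid,left,both,-0.80
H_prot,acid,right,both,-0.51
H_prot,base,left,both,0.80
H_prot,base,right,both,0.83
H_deprot,acid,left,both,0.00
H_deprot,acid,right,both,0.00
H_deprot,base,left,both,-0.10
H_deprot,base,right,both,0.14
I,acid,left,both,-0.91
I,acid,right,both,-0.59
I,base,left,both,-0.73
I,base,right,both,-0.23
L,acid,left,both,-0.57
L,acid,right,both,-0.13
L,base,left,both,-0.58
L,base,right,both,-0.21
K,acid,left,both,-0.56
K,acid,right,both,-0.29
K,base,left,both,-0.04
K,base,right,both,0.12
M,acid,left,both,-0.64
M,acid,right,both,-0.28
M,base,left,both,-0.01
M,base,right,both,0.11
F,acid,left,both,-0.52
F,acid,right,both,-0.43
F,base,left,both,-0.24
F,base,right,both,0.06
P,acid,left,both,0.00
P,acid,right,both,-0.19
P,base,left,both,0.00
P,base,right,both,-0.24
S,acid,left,both,-0.44
S,acid,right,both,-0.39
S,base,left,both,0.37
S,base,right,both,0.30
T,acid,left,both,-0.79
T,acid,right,both,-0.47
T,base,left,both,-0.07
T,base,right,both,0.20
W,acid,left,both,-0.40
W,acid,right,both,-0.44
W,base,left,both,-0.41
W,base,right,both,-0.11
Y,acid,left,both,-0.41
Y,acid,right,both,-0.37
Y,base,left,both,-0.27
Y,base,right,both,0.05
V,acid,left,both,-0.74
V,acid,right,both,-0.30
V,base,left,both,-0.70
V,base,right,both,-0.14
NT,acid,right,both,-1.32
NT,base,right,both,1.62
CT_prot,acid,left,both,0.96
CT_prot,base,left,both,0.00
CT_deprot,acid,left,both,0.05
CT_deprot,base,left,both,-1.80
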