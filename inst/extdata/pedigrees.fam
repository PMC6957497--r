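fam20 g1 0 0 1 -9
fam20 g2 0 0 2 -9
fam20 p1 g1 g2 1 -9
fam20 p2 g1 g2 2 -9
fam20 p3 g1 g2 1 -9
fam20 p4 g1 g2 2 -9
fam20 s1 0 0 2 -9
fam20 s2 0 0 1 -9
fam20 s3 0 0 2 -9
fam20 k1 p1 s1 1 -9
fam20 k2 p1 s1 2 -9
fam20 k3 p1 s1 1 -9
fam20 k4 p1 s1 2 -9
fam20 k5 s2 p2 1 -9
fam20 k6 s2 p2 2 -9
fam20 k7 s2 p2 1 -9
fam20 k8 s2 p2 2 -9
fam20 k9 p3 s3 1 -9
fam20 k10 p3 s3 2 -9
fam20 k11 p3 s3 1 -9
fam10 g1 0 0 1 -9
fam10 g2 0 0 2 -9
fam10 p1 g1 g2 1 -9
fam10 p2 g1 g2 2 -9
fam10 p3 g1 g2 1 -9
fam10 s1 0 0 2 -9
fam10 s2 0 0 1 -9
fam10 k1 p1 s1 1 -9
fam10 k2 p1 s1 2 -9
fam10 k3 s2 p2 1 -9
fam4 p1 0 0 1 -9
fam4 p2 0 0 2 -9
fam4 c1 p1 p2 1 -9
fam4 c2 p1 p2 2 -9
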