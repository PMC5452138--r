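# Simplified nearest-neighbour free-energy parameters (kcal/mol, 37 C).
# [stack]: outer-pair inner-pair dG, outer = (i,j), inner = (i+1,j-1);
#          the table satisfies stack(P,Q) = stack(rev(Q),rev(P)).
# [hairpin]/[bulge]/[internal]: loop-size penalty tables; sizes beyond the
#          table extrapolate as E(last) + loop_coef * ln(size/last).
# [multiloop]: a (closing) b (per branch) c (per unpaired base).

[stack]
AU AU  -0.93
AU UA  -1.10
AU GC  -2.08
AU CG  -2.24
AU GU  -0.55
AU UG  -1.36
UA AU  -1.33
UA UA  -0.93
UA GC  -2.11
UA CG  -2.35
UA GU  -1.27
UA UG  -1.00
GC AU  -2.35
GC UA  -2.24
GC GC  -3.26
GC CG  -3.42
GC GU  -1.53
GC UG  -2.11
CG AU  -2.11
CG UA  -2.08
CG GC  -2.36
CG CG  -3.26
CG GU  -1.41
CG UG  -2.51
GU AU  -1.00
GU UA  -1.36
GU GC  -2.51
GU CG  -2.11
GU GU  -0.50
GU UG   1.29
UG AU  -1.27
UG UA  -0.55
UG GC  -1.41
UG CG  -1.53
UG GU   0.30
UG UG  -0.50

[hairpin]
3 5.40
4 5.60
5 5.70
6 5.40
7 6.00
8 5.50
9 6.40
10 6.51
11 6.62
12 6.71
13 6.80
14 6.88
15 6.95
16 7.02
17 7.09
18 7.15
19 7.21
20 7.26
21 7.32
22 7.37
23 7.41
24 7.46
25 7.50
26 7.55
27 7.59
28 7.63
29 7.66
30 7.70

[bulge]
1 3.80
2 2.80
3 3.20
4 3.60
5 4.00
6 4.40
7 4.57
8 4.71
9 4.84
10 4.95
11 5.05
12 5.15
13 5.24
14 5.32
15 5.39
16 5.46
17 5.52
18 5.59
19 5.64
20 5.70
21 5.75
22 5.80
23 5.85
24 5.90
25 5.94
26 5.98
27 6.02
28 6.06
29 6.10
30 6.14

[internal]
2 1.50
3 1.60
4 1.70
5 1.80
6 2.00
7 2.17
8 2.31
9 2.44
10 2.55
11 2.65
12 2.75
13 2.84
14 2.92
15 2.99
16 3.06
17 3.12
18 3.19
19 3.24
20 3.30
21 3.35
22 3.40
23 3.45
24 3.50
25 3.54
26 3.58
27 3.62
28 3.66
29 3.70
30 3.74

[multiloop]
a 3.40
b 0.40
c 0.10

[options]
min_loop 3
max_internal 30
loop_coef 1.08
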