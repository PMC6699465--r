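model	variant	b	a	ci_low	ci_high	mse
Dayhoff	PC	1.00000	1.99924	1.99850	1.99997	0.00121
BLOSUM62	PC	1.00000	3.24334	3.24188	3.24481	0.00064
JTT	PC	1.00000	2.57163	2.57057	2.57270	0.00089
mtREV	PC	1.00000	1.23867	1.23812	1.23922	0.00496
mtMam	PC	1.00000	0.90348	0.90324	0.90372	0.00365
cpREV	PC	1.00000	1.98628	1.98556	1.98699	0.00119
VT	PC	1.00000	3.41801	3.41628	3.41975	0.00072
WAG	PC	1.00000	2.69788	2.69665	2.69910	0.00096
WAG*	PC	1.00000	2.80430	2.80305	2.80555	0.00084
rtREV	PC	1.00000	2.08011	2.07936	2.08087	0.00107
PMB	PC	1.00000	3.45924	3.45765	3.46084	0.00059
DCMut-Dayhoff	PC	1.00000	2.01070	2.00996	2.01144	0.00120
DCMut-JTT	PC	1.00000	2.55191	2.55086	2.55295	0.00088
HIVb	PC	1.00000	1.83588	1.83529	1.83646	0.00110
HIVw	PC	1.00000	1.62839	1.62776	1.62902	0.00210
MtArt	PC	1.00000	0.93628	0.93602	0.93653	0.00345
LG	PC	1.00000	2.21046	2.20952	2.21140	0.00129
MtZoa	PC	1.00000	1.05466	1.05439	1.05492	0.00235
cpREV64	PC	1.00000	2.63503	2.63381	2.63625	0.00103
FLU	PC	1.00000	1.52820	1.52775	1.52865	0.00144
gcpREV	PC	1.00000	1.76147	1.76090	1.76205	0.00128
stmtREV	PC	1.00000	2.03813	2.03719	2.03908	0.00184
AB	PC	1.00000	1.71521	1.71480	1.71562	0.00075
mtInv	PC	1.00000	1.57997	1.57919	1.58076	0.00373
mtMet	PC	1.00000	1.40469	1.40420	1.40518	0.00240
mtVer	PC	1.00000	1.15596	1.15558	1.15634	0.00330
DEN	PC	1.00000	2.12834	2.12753	2.12915	0.00111
Dayhoff	EI	0.93993	3.14582	3.14550	3.14613	0.00005
BLOSUM62	EI	0.94151	6.32690	6.32599	6.32782	0.00002
JTT	EI	0.94191	4.39688	4.39633	4.39744	0.00004
mtREV	EI	0.92467	1.95601	1.95578	1.95623	0.00024
mtMam	EI	0.92473	1.30527	1.30514	1.30539	0.00040
cpREV	EI	0.93916	3.14971	3.14940	3.15002	0.00005
VT	EI	0.94092	6.96847	6.96714	6.96980	0.00003
WAG	EI	0.94055	4.81653	4.81579	4.81726	0.00005
WAG*	EI	0.94055	5.01598	5.01518	5.01679	0.00005
rtREV	EI	0.94024	3.30578	3.30545	3.30612	0.00005
PMB	EI	0.94195	7.10575	7.10459	7.10691	0.00002
DCMut-Dayhoff	EI	0.93993	3.16983	3.16951	3.17015	0.00005
DCMut-JTT	EI	0.94193	4.36663	4.36607	4.36719	0.00004
HIVb	EI	0.94179	2.77572	2.77550	2.77594	0.00004
HIVw	EI	0.93819	2.45611	2.45584	2.45639	0.00012
MtArt	EI	0.92743	1.35206	1.35186	1.35226	0.00095
LG	EI	0.94051	3.56820	3.56767	3.56873	0.00009
MtZoa	EI	0.92686	1.57251	1.57227	1.57275	0.00068
cpREV64	EI	0.93948	4.64357	4.64279	4.64436	0.00006
FLU	EI	0.94110	2.22717	2.22704	2.22731	0.00005
gcpREV	EI	0.93745	2.72778	2.72755	2.72800	0.00005
stmtREV	EI	0.92778	3.77358	3.77322	3.77395	0.00004
AB	EI	0.93407	2.78549	2.78473	2.78625	0.00058
mtInv	EI	0.92211	2.85866	2.85835	2.85897	0.00011
mtMet	EI	0.92546	2.34419	2.34387	2.34451	0.00024
mtVer	EI	0.92052	1.91274	1.91241	1.91307	0.00067
DEN	EI	0.94143	3.34672	3.34632	3.34712	0.00006
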