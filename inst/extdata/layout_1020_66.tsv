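name	role	x	y	z
FP1	scalp	-0.0294	0.0839	-0.0070
FPZ	scalp	0.0001	0.0882	-0.0017
FP2	scalp	0.0299	0.0849	-0.0071
AF7	scalp	-0.0548	0.0686	-0.0106
AF3	scalp	-0.0337	0.0768	0.0212
AF4	scalp	0.0357	0.0777	0.0220
AF8	scalp	0.0557	0.0697	-0.0108
F7	scalp	-0.0703	0.0425	-0.0114
F5	scalp	-0.0645	0.0480	0.0169
F3	scalp	-0.0502	0.0531	0.0422
F1	scalp	-0.0275	0.0569	0.0603
FZ	scalp	0.0003	0.0585	0.0665
F2	scalp	0.0295	0.0576	0.0595
F4	scalp	0.0518	0.0543	0.0408
F6	scalp	0.0679	0.0498	0.0164
F8	scalp	0.0730	0.0444	-0.0120
FT7	scalp	-0.0808	0.0141	-0.0111
FC5	scalp	-0.0772	0.0186	0.0245
FC3	scalp	-0.0602	0.0227	0.0555
FC1	scalp	-0.0341	0.0260	0.0800
FCZ	scalp	0.0004	0.0274	0.0887
FC2	scalp	0.0348	0.0264	0.0788
FC4	scalp	0.0623	0.0237	0.0556
FC6	scalp	0.0795	0.0199	0.0244
FT8	scalp	0.0818	0.0154	-0.0113
T7	scalp	-0.0842	-0.0160	-0.0093
C5	scalp	-0.0803	-0.0138	0.0292
C3	scalp	-0.0654	-0.0116	0.0644
C1	scalp	-0.0362	-0.0100	0.0898
CZ	scalp	0.0004	-0.0092	0.1002
C2	scalp	0.0377	-0.0096	0.0884
C4	scalp	0.0671	-0.0109	0.0636
C6	scalp	0.0835	-0.0128	0.0292
T8	scalp	0.0851	-0.0150	-0.0095
TP7	scalp	-0.0848	-0.0460	-0.0071
CP5	scalp	-0.0796	-0.0466	0.0309
CP3	scalp	-0.0636	-0.0470	0.0656
CP1	scalp	-0.0355	-0.0473	0.0913
CPZ	scalp	0.0004	-0.0473	0.0994
CP2	scalp	0.0384	-0.0471	0.0907
CP4	scalp	0.0666	-0.0466	0.0656
CP6	scalp	0.0833	-0.0461	0.0312
TP8	scalp	0.0855	-0.0455	-0.0071
TP9	scalp	-0.0856	-0.0465	-0.0457
TP10	scalp	0.0862	-0.0470	-0.0459
P7	scalp	-0.0724	-0.0735	-0.0025
P5	scalp	-0.0673	-0.0763	0.0284
P3	scalp	-0.0530	-0.0788	0.0559
P1	scalp	-0.0286	-0.0805	0.0754
PZ	scalp	0.0003	-0.0811	0.0826
P2	scalp	0.0319	-0.0805	0.0767
P4	scalp	0.0557	-0.0786	0.0566
P6	scalp	0.0679	-0.0759	0.0281
P8	scalp	0.0731	-0.0731	-0.0025
PO7	scalp	-0.0548	-0.0975	0.0028
PO5	scalp	-0.0484	-0.0993	0.0216
PO3	scalp	-0.0365	-0.1009	0.0372
POZ	scalp	0.0002	-0.1022	0.0506
PO4	scalp	0.0368	-0.1008	0.0364
PO6	scalp	0.0498	-0.0994	0.0217
PO8	scalp	0.0557	-0.0976	0.0027
O1	scalp	-0.0294	-0.1124	0.0088
OZ	scalp	0.0001	-0.1149	0.0147
O2	scalp	0.0298	-0.1122	0.0088
HEOG	eog	0.0600	0.0750	-0.0300
VEOG	eog	-0.0300	0.0950	-0.0250
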