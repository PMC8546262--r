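label	x	y	z
Fp1	-0.293699	0.955821	0.012123
Fp2	0.270719	0.962611	0.009529
F7	-0.769909	0.635018	-0.063177
F8	0.757122	0.649225	-0.072614
FT9	-0.828844	0.327599	-0.453538
FT10	0.816583	0.338593	-0.467489
FTT9h	-0.937823	0.175063	-0.299734
FTT10h	0.931563	0.188296	-0.311024
T7	-0.995812	0.003928	-0.091335
T8	0.994521	0.026257	-0.101190
TTP7h	-0.975333	-0.177187	0.131645
TTP8h	0.978823	-0.160376	0.127223
TP7	-0.941163	-0.327455	-0.083575
TP8	0.944232	-0.315938	-0.092782
TPP9h	-0.843827	-0.462864	-0.271501
TPP10h	0.842762	-0.459510	-0.280361
P9	-0.724727	-0.540824	-0.426944
P10	0.720118	-0.539811	-0.435929
I1	-0.283636	-0.902196	-0.324950
I2	0.276208	-0.902758	-0.329754
Cz	-0.000000	-0.000000	1.000000
FCz	-0.002565	0.373232	0.927735
CPz	0.001602	-0.360923	0.932594
C1	-0.372163	-0.002814	0.928163
C2	0.383370	0.005768	0.923577
FFC1h	-0.161306	0.540019	0.826051
Fz	-0.005677	0.693088	0.720830
AFF1	-0.241705	0.809811	0.534588
PPO4	0.467228	-0.771479	0.431877
PPO3	-0.460643	-0.775421	0.431891
FFC4	0.601789	0.560751	0.568690
FC5h	-0.787391	0.367712	0.494777
POOz	-0.000433	-0.960948	0.276729
CP4	0.672272	-0.351435	0.651570
CP3	-0.654055	-0.365055	0.662530
AF9	-0.478430	0.788901	-0.385668
AF10	0.465794	0.792765	-0.393140
PO8	0.562604	-0.826477	-0.020321
FCC6h	0.830714	0.203415	0.518205
PO7	-0.560225	-0.828206	-0.014933
CPP5	-0.797795	-0.518413	0.307850
CPP6	0.811864	-0.500832	0.300072
CPP2	0.337102	-0.516111	0.787396
AF2	0.179475	0.903624	0.388913
P1h	-0.133390	-0.666244	0.733707
FC3h	-0.517724	0.373647	0.769642
C5h	-0.837582	-0.002468	0.546306
OIz	-0.002644	-0.995356	-0.096222
AFF5h	-0.527112	0.793369	0.304496
FT7h	-0.925013	0.360186	0.120899
AFF6h	0.516809	0.803187	0.296308
FC2	0.352405	0.384170	0.853360
FT8h	0.916919	0.383417	0.110685
CP1	-0.343564	-0.361177	0.866900
TTP9	-0.876240	-0.122380	-0.466076
POO6h	0.319125	-0.932631	0.168402
POO5h	-0.320051	-0.930566	0.177805
PPO2h	0.133500	-0.783993	0.606245
AFp1h	-0.068526	0.969830	0.233953
F2	0.286609	0.697271	0.657015
F9	-0.688525	0.585736	-0.427605
F10	0.677680	0.593075	-0.434756
PO10	0.523194	-0.759504	-0.386552
AF8	0.531833	0.846024	-0.037375
PO9	-0.529555	-0.759065	-0.378671
AF7	-0.550850	0.833982	-0.032222
C4	0.717084	0.012551	0.696874
C6	0.939218	0.020042	0.342736
CCP6h	0.833905	-0.168389	0.525592
P7	-0.784998	-0.617165	-0.053716
FCC3	-0.700528	0.187632	0.688516
P8	0.788750	-0.611667	-0.061122
FCC5	-0.921035	0.186325	0.342019
TTP10h	0.941597	-0.146801	-0.303060
FCC4h	0.547872	0.203516	0.811430
CCP4h	0.553853	-0.177280	0.813523
FFC3	-0.604234	0.542292	0.583799
FFC5	-0.798488	0.530164	0.285207
FCC1h	-0.189513	0.188621	0.963591
CCP2h	0.195291	-0.183372	0.963450
FCC2h	0.186620	0.194926	0.962900
CCP3h	-0.541758	-0.188823	0.819051
FFC6	0.793241	0.546608	0.268306
PPO6	0.618995	-0.753947	0.220020
CCP1h	-0.183149	-0.187034	0.965129
CPP3h	-0.460753	-0.526712	0.714340
PPO5	-0.606181	-0.764087	0.220717
PO1	-0.191734	-0.888186	0.417569
FFC2h	0.167052	0.543381	0.822697
FFT10h	0.822929	0.491572	-0.284859
FFT9h	-0.834235	0.476984	-0.276655
AFF9h	-0.649789	0.720868	-0.241088
AFF10h	0.633259	0.733591	-0.246632
PO2	0.197440	-0.887995	0.415311
TP10	0.843242	-0.268732	-0.465538
P4h	0.430987	-0.655761	0.619861
F3h	-0.416103	0.685236	0.597753
CCP5	-0.920425	-0.185114	0.344312
O1h	-0.149406	-0.986893	0.060998
P6h	0.644896	-0.648655	0.404173
AFp9h	-0.422986	0.885245	-0.193454
AFp10h	0.401012	0.894707	-0.196694
AF3	-0.342746	0.895329	0.284449
O2h	0.147471	-0.987256	0.059815
POO10h	0.421697	-0.888592	-0.180486
P5h	-0.632134	-0.658555	0.408304
PPO10h	0.659299	-0.714200	-0.235040
AFF4h	0.345513	0.810462	0.473045
AFF2h	0.121383	0.814637	0.567127
FT7	-0.933366	0.348565	-0.085619
FT8	0.922814	0.373467	-0.094531
AFp4h	0.169496	0.967454	0.187891
PPO9h	-0.661448	-0.714350	-0.228452
POO9h	-0.422661	-0.888772	-0.177320
CP5h	-0.779269	-0.363153	0.510745
FCC4	0.703395	0.205850	0.680339
FC4	0.663465	0.390672	0.638114
AF1h	-0.099429	0.904989	0.413654
FCC3h	-0.546079	0.188553	0.816239
AF5	-0.463606	0.875820	0.134194
TPP7h	-0.853082	-0.506810	0.124073
FCC2	0.372506	0.200391	0.906136
C3	-0.706839	-0.003315	0.707367
POz	0.000497	-0.890371	0.455236
FCC1	-0.373565	0.188033	0.908346
AF6	0.447908	0.884456	0.130829
FC6h	0.784982	0.385676	0.484828
FCC6	0.919253	0.208269	0.334064
nasion	-0.000000	0.968563	-0.248770
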