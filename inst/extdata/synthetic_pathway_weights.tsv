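pathway	gene	weight
TNFa	EXP1995	-0.5997
TNFa	EXP1876	-0.3932
TNFa	EXP1650	0.9727
TNFa	EXP0102	-0.795
TNFa	EXP0504	-0.5501
TNFa	EXP1071	-0.5055
TNFa	EXP1772	-0.2692
TNFa	EXP0145	0.5057
TNFa	EXP0342	-0.8335
TNFa	EXP0227	-0.9779
TNFa	EXP0513	-0.9748
TNFa	EXP1448	-0.081
TNFa	EXP0970	-0.2447
TNFa	EXP0561	0.0121
TNFa	EXP0823	-0.3466
NFkB	EXP0272	-0.089
NFkB	EXP0889	0.2314
NFkB	EXP0466	0.2249
NFkB	EXP1089	0.9647
NFkB	EXP1060	-0.6086
NFkB	EXP0868	0.9452
NFkB	EXP0237	-0.5778
NFkB	EXP1250	0.4127
NFkB	EXP1051	0.7215
NFkB	EXP1465	-0.6126
NFkB	EXP0476	-0.4676
NFkB	EXP0864	0.3227
NFkB	EXP1416	0.1595
NFkB	EXP0625	0.4844
NFkB	EXP1781	0.8113
TGFb	EXP1728	0.4935
TGFb	EXP1522	-0.166
TGFb	EXP1609	-0.8688
TGFb	EXP1058	0.8626
TGFb	EXP0828	-0.5598
TGFb	EXP1422	0.3826
TGFb	EXP1517	-0.1443
TGFb	EXP1172	-0.9033
TGFb	EXP1874	0.2555
TGFb	EXP1701	0.3634
TGFb	EXP1677	0.7441
TGFb	EXP1512	-0.8153
TGFb	EXP1446	-0.9944
TGFb	EXP1421	0.2482
TGFb	EXP1682	0.2128
Estrogen	EXP0210	-0.7793
Estrogen	EXP0401	-0.9542
Estrogen	EXP0417	-0.2832
Estrogen	EXP1114	-0.7438
Estrogen	EXP0009	0.5863
Estrogen	EXP1297	0.9033
Estrogen	EXP0458	0.2498
Estrogen	EXP0218	-0.9698
Estrogen	EXP0232	-0.9999
Estrogen	EXP0837	0.4608
Estrogen	EXP1711	-0.6792
Estrogen	EXP0734	-0.9101
Estrogen	EXP0451	-0.7263
Estrogen	EXP0213	-0.6991
Estrogen	EXP0735	0.9702
p53	EXP1389	-0.0149
p53	EXP1092	-0.0901
p53	EXP0073	-0.8325
p53	EXP1977	-0.5959
p53	EXP0168	0.2983
p53	EXP0101	-0.6238
p53	EXP1497	-0.3609
p53	EXP0906	0.0567
p53	EXP1558	0.5999
p53	EXP1375	0.7808
p53	EXP0112	-0.4828
p53	EXP0457	-0.6046
p53	EXP1498	-0.5433
p53	EXP1615	-0.9931
p53	EXP0148	0.3531
Hypoxia	EXP1312	0.0499
Hypoxia	EXP0143	-0.4364
Hypoxia	EXP1566	0.9099
Hypoxia	EXP1340	0.7711
Hypoxia	EXP1225	0.0476
Hypoxia	EXP0924	-0.963
Hypoxia	EXP1688	0.3683
Hypoxia	EXP1734	-0.5532
Hypoxia	EXP1390	0.9117
Hypoxia	EXP1181	-0.0414
Hypoxia	EXP0494	-0.0619
Hypoxia	EXP0381	0.5385
Hypoxia	EXP0049	0.8512
Hypoxia	EXP0218	-0.7573
Hypoxia	EXP0074	0.209
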