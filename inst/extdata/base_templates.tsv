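base	atom	element	x	y	z
G	P	P	4.0970	-4.8389	-1.7115
G	O4'	O	1.9538	-1.1894	-0.6388
G	C2'	C	1.9883	-0.0053	1.4494
G	C1'	C	1.4640	0.0000	0.0009
G	N9	N	0.0000	0.0000	0.0000
G	C8	C	-0.8062	-1.1002	0.0003
G	N7	N	-2.0549	-0.7329	-0.0008
G	C5	C	-2.1239	0.6207	-0.0018
G	C6	C	-3.1877	1.5531	-0.0031
G	O6	O	-4.3471	1.1771	-0.0037
G	N1	N	-2.8861	2.8696	0.0036
G	C2	C	-1.5869	3.2786	-0.0019
G	N2	N	-1.3112	4.6224	-0.0029
G	N3	N	-0.5899	2.4226	-0.0020
G	C4	C	-0.8096	1.1029	-0.0001
G	H1'	H	1.8345	0.8817	-0.5229
G	H8	H	-0.4602	-2.1239	0.0007
G	H1	H	-3.5994	3.5275	0.0023
G	H21	H	-0.3910	4.9288	-0.0026
G	H22	H	-2.0365	5.2667	-0.0079
C	P	P	4.0924	3.3280	3.9131
C	O4'	O	1.9529	0.7094	1.1512
C	C2'	C	1.9900	0.7326	-1.2489
C	C1'	C	1.4647	-0.0000	0.0013
C	N1	N	0.0000	0.0000	0.0000
C	C2	C	-0.6686	1.1663	0.0005
C	O2	O	-0.0455	2.2154	0.0025
C	N3	N	-2.0004	1.1954	-0.0003
C	C4	C	-2.7025	0.0707	-0.0016
C	N4	N	-4.0776	0.1125	-0.0017
C	C5	C	-2.0310	-1.1687	0.0020
C	C6	C	-0.6777	-1.1819	-0.0019
C	H1'	H	1.8356	-1.0249	0.0128
C	H41	H	-4.5361	0.9671	-0.0007
C	H42	H	-4.5882	-0.7121	-0.0073
C	H5	H	-2.5884	-2.0946	0.0006
C	H6	H	-0.1413	-2.1188	-0.0035
A	P	P	4.0946	-4.8388	-1.7179
A	O4'	O	1.9528	-1.1894	-0.6412
A	C2'	C	1.9897	-0.0074	1.4482
A	C1'	C	1.4655	0.0000	-0.0004
A	N9	N	0.0000	0.0000	0.0000
A	C8	C	-0.8057	-1.0980	-0.0012
A	N7	N	-2.0546	-0.7327	-0.0018
A	C5	C	-2.1296	0.6199	0.0048
A	C6	C	-3.1804	1.5519	-0.0015
A	N6	N	-4.4991	1.1320	-0.0028
A	N1	N	-2.8792	2.8464	-0.0009
A	C2	C	-1.6250	3.2555	-0.0005
A	N3	N	-0.6083	2.4200	-0.0002
A	C4	C	-0.8111	1.1061	-0.0009
A	H1'	H	1.8355	0.8820	-0.5235
A	H8	H	-0.4594	-2.1204	-0.0014
A	H61	H	-5.2162	1.7851	-0.0025
A	H62	H	-4.7062	0.1838	-0.0067
A	H2	H	-1.4249	4.3170	-0.0010
T	P	P	1.3548	5.3923	0.3210
T	O4'	O	1.9092	1.1364	0.7338
T	C2'	C	2.0223	0.0850	-1.3993
T	C1'	C	1.4341	0.0000	-0.0003
T	N1	N	0.0000	0.0000	0.0000
T	C2	C	-0.7320	-1.2067	-0.0002
T	O2	O	-0.2123	-2.3242	0.0001
T	N3	N	-2.1225	-1.0559	-0.0005
T	C4	C	-2.8324	0.1353	0.0003
T	O4	O	-4.0588	0.1955	0.0012
T	C5	C	-1.9929	1.3629	-0.0005
T	C7	C	-2.6844	2.6883	-0.0009
T	C6	C	-0.6608	1.2218	-0.0002
T	H1'	H	1.7682	-0.9034	0.5214
T	H3	H	-2.6702	-1.9113	-0.0002
T	H6	H	-0.0115	2.0923	-0.0003
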