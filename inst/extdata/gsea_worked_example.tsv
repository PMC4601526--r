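name	rank	score	running	core
mir-34a	0	34.82690048	0.19905818	Yes
mir-34c	1	34.6026001	0.3968343	Yes
mir-486	19	18.5720005	0.49173445	Yes
mir-139	32	16.42160034	0.5776527	Yes
let-7a-2	76	12.94890022	0.623206	Yes
mir-125b-1	101	11.50020027	0.67305356	Yes
mir-365a	323	6.691860199	0.5650411	No
mir-215	389	6.109330177	0.556942	No
mir-96	524	5.189610004	0.497921	No
let-7a-1	651	4.54610014	0.44051638	No
mir-423	759	3.868499994	0.39181334	No
mir-1247	789	3.651760101	0.3934929	No
mir-192	872	3.154949903	0.35725677	No
mir-191	877	3.117209911	0.3724264	No
mir-3184	901	3.018699884	0.3744585	No
mir-152	1051	2.350739956	0.2892843	No
mir-1-2	1084	2.201610088	0.2806899	No
mir-148b	1111	2.113770008	0.27556428	No
mir-125b-2	1520	0.065534301	0.005919015	No
let-7a-3	1529	0.00653213	0.000662	No
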