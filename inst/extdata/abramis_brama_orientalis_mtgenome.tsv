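Feature	Position	Length	Intergenic	Initiation	Stop	Anticodon	Strand
trnF	1-69	69				GAA	H
rrnS	70-1026	957					H
trnV	1029-1100	72	2			TAC	H
rrnL	1120-2766	1647	19				H
trnL2	2792-2867	76	25			TAA	H
nad1	2869-3843	975	1	ATG	TAA		H
trnI	3848-3919	72	4			GAT	H
trnQ	3918-3988	71	-2			TTG	L
trnM	3990-4058	69	1			CAT	H
nad2	4059-5105	1047		ATG	TAG		H
trnW	5104-5174	71	1			TCA	H
trnA	5176-5244	69	-2			TGG	L
trnN	5246-5318	73	1			GTT	L
OL	5321-5351	31	2				H
trnC	5351-5417	67	-1			GCA	L
trnY	5419-5489	71	1			GTA	L
cox1	5491-7041	1551	1	GTG	TAA		H
trnS2	7042-7112	71				TGA	L
trnD	7116-7189	74	3			GTC	H
cox2	7203-7907	705	13	ATG	TAA		H
trnK	7894-7969	76	-14			TTT	H
atp8	7971-8135	165	1	ATG	TAG		H
atp6	8129-8812	684	-7	ATG	TAA		H
cox3	8812-9651	840	-1	ATG	TAA		H
trnG	9596-9667	72	-56			TCC	H
nad3	9668-10,018	351		ATG	TAG		H
trnR	10,017-10,085	69	-2			TCG	H
nad4L	10,086-10,382	297		ATG	TAA		H
nad4	10,376-11,758	1383	-7	ATG	TAG		H
trnH	11,758-11,826	69	-1			GTG	H
trnS1	11,827-11,895	69				GCT	H
trnL1	11,897-11,969	73	1			TAG	H
nad5	11,970-13,805	1836		ATG	TAA		H
nad6	13,802-14,323	522	-4	ATG	TAA		L
trnE	14,324-14,392	69				TTC	L
cytb	14,395-15,535	1141	2	ATG	T		H
trnT	15,536-15,607	72				TGT	H
trnP	15,607-15,676	70	-1			TGG	L
NCR	15,703-16,607	905	26				H
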