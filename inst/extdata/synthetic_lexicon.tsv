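word	happiness_rank	happiness_average	happiness_standard_deviation
ain't	29	3.3	NA
alone	30	3.2	NA
amazing	8	7.8	NA
and	21	5.22	NA
angry	42	2.26	NA
animals	19	6	NA
ass	34	3	NA
beach	13	7.52	NA
beautiful	5	7.92	NA
bitch	35	2.9	NA
broke	35	2.9	NA
crash	38	2.6	NA
damn	31	3.1	NA
dead	49	1.54	NA
dinner	17	7.1	NA
excited	15	7.3	NA
failed	46	2.1	NA
family	12	7.6	NA
finna	27	3.5	NA
fired	39	2.5	NA
friend	11	7.66	NA
fuck	25	4.14	NA
fun	4	7.96	NA
going	23	5.11	NA
gone	28	3.42	NA
happy	3	8.3	NA
hell	43	2.2	NA
holiday	8	7.8	NA
jail	47	1.9	NA
laughter	1	8.5	NA
lost	37	2.76	NA
love	2	8.42	NA
music	10	7.67	NA
nobody	33	3.08	NA
pain	45	2.13	NA
party	16	7.2	NA
sad	41	2.38	NA
shit	39	2.5	NA
sick	43	2.2	NA
smile	7	7.89	NA
street	21	5.22	NA
sunshine	6	7.9	NA
the	24	4.98	NA
tired	31	3.1	NA
today	20	5.3	NA
tryna	26	3.6	NA
war	48	1.8	NA
weekend	14	7.45	NA
winning	18	7	NA
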