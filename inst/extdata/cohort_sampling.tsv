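row_type	biotype	country	locality	lat	long	age_class	noi	probe_donors	nomka	noge	noagm
record	EE	Hungary	Szodrakosz Cr.	47°43'58.8"N	19°07'58.8"E	none	1	0	5	-	-
record	EE	Poland	Budkowiczanka R.	50°50'50.1"N	18°11'07.1"E	none	1	1	-	-	-
record	TT	Germany	Haaren Cr.	53°04'58.8"N	7°49'58.8"E	none	3	2	4	-	-
record	NN	Romania	Danube R.	44°04'47.9"N	26°43'51.2"E	none	2	2	-	-	-
record	NN	Romania	Sinoe at Histria	44°37'58.8"N	28°52'58.8"E	none	1	0	4	-	-
record	ET	Czech Rep.	Laboratory F1	50°24'37.6"N	14°27'16.9"E	F1	1	0	9	1	4
record	ET	Poland	Dolna Barycz R.	51°36'59.1"N	16°30'49.1"E	Holocene	4	0	27	2	4
total	ET						5	0	36	3	8
record	EN	Bulgaria	Jantra R.	43°09'58.0"N	25°55'53.8"E	hybrid clade I	2	0	22	1	1
record	EN	Romania	Danube R.	44°04'47.9"N	26°43'51.2"E	hybrid clade I	3	0	15	2	9
total	EN						5	0	37	3	10
record	EET	Germany	Neisse R.	51°51'28.8"N	14°36'34.9"E	Holocene	1	0	12	1	8
record	EET	Poland	Polska Woda R.	51°31'17.0"N	17°30'07.0"E	Holocene	3	0	16	-	-
record	EET	Poland	Dolna Barycz R.	51°36'59.1"N	16°30'49.1"E	Holocene	2	0	5	1	2
record	EET	Czech Rep.	Pšovka Cr.	50°22'11.8"N	14°33'06.8"E	Holocene	1	0	2	-	-
total	EET						7	0	35	2	10
record	ETT	Germany	Issel R.	51°51'00.0"N	06°15'00.0"E	Holocene	2	0	13	2	3
record	ETT	Germany	Ilmenau R.	53°22'34.0"N	10°14'36.5"E	Holocene	1	0	2	-	-
record	ETT	Czech Rep.	Laboratory B1	50°24'37.6"N	14°27'16.9"E	B1	3	0	17	2	10
total	ETT						6	0	32	4	13
record	EEN	Bulgaria	Vit R.	43°15'47.0"N	24°19'30.1"E	hybrid clade I	2	0	56	2	6
record	EEN	Poland	Polska Woda R.	51°31'17.0"N	17°30'07.0"E	hybrid clade I	1	0	7	1	1
record	EEN	Romania	Barlat R.	46°40'23.8"N	27°40'07.5"E	Holocene	3	0	6	-	-
record	EEN	Romania	Comana R.	44°10'07.1"N	26°08'54.9"E	hybrid clade I	1	0	2	-	-
record	EEN	Romania	Adjud R.	46°04'21.0"N	27°12'32.2"E	Holocene	1	0	2	-	-
record	EEN	Slovakia	Cierna voda R.	48°36'27.0"N	21°59'34.1"E	hybrid clade I	8	0	51	5	17
total	EEN						16	0	124	8	24
record	ENN	Romania	Danube R.	44°04'47.9"N	26°43'51.2"E	Holocene	10	0	35	3	12
total	ENN						10	0	35	3	12
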