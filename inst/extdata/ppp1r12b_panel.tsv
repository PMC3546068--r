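label	site	start	stop	sequence	mods	ambiguity	internal_standard	quantifiers	precursor_charge
Ser29	Ser29	28	38	GSLTEQEPAER	phospho@2		0	y8/+1;y9/+1	2
Ser504	Ser504	501	511	KLNSTSDIEEK	phospho@4		0	b4/+1;y7/+1	2
Ser645/T646	Ser645/T646	645	659	STQGVTLTDLQEAER		1,2	0	b2/+1;b3/+1;b4/+1;b5/+1;y10/+1;y11/+1;y12/+1;y13/+1	2
Ser711	Ser711	711	720	SLDEEPICHR	phospho@1		0	y6/+1;y7/+1;y8/+1	2
Ser760	Ser760	755	773	FSVPDSESSETTTNTTTAK	phospho@6		0	b7/+1;y12/+1;y13/+1	2
Ser839	Ser839	837	853	LESGGSNPTTSDSYGDR	phospho@3		0	b3/+1;y12/+1;y13/+1;y14/+1	2
IS_LGQTPFDVADEGLVEHLELLQK		282	303	LGQTPFDVADEGLVEHLELLQK			1	prec/+3;prec/+2	3
IS_IQSGFFK		327	333	IQSGFFK			1	prec/+2;prec/+1	2
IS_SSITEQIPAPAQNTFSASSAR		397	417	SSITEQIPAPAQNTFSASSAR			1	prec/+3;prec/+2	3
IS_SYISSLAPR		492	500	SYISSLAPR			1	prec/+2;prec/+1	2
IS_ESAVNLVR		515	522	ESAVNLVR			1	prec/+2;prec/+1	2
IS_PSLYTSSHLLWTNR		741	754	PSLYTSSHLLWTNR			1	prec/+3;prec/+2	3
IS_LESGGSNPTTSDSYGDR		837	853	LESGGSNPTTSDSYGDR			1	prec/+2	2
IS_LKDENGALIR		966	975	LKDENGALIR			1	prec/+2;prec/+1	2
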