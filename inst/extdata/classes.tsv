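unit_id	class_id	subclass_id	type_group	architecture	variant_architectures	notes
I	I	.	I	Myosin_head-IQ-Myosin_TH1	.	class-level unit for members outside the named subclasses
Ia/b	I	Ia/b	I	Myosin_head-IQ-Myosin_TH1	.	0-2 IQ repeats
Ic/h	I	Ic/h	I	Myosin_head-IQ-Myosin_TH1	.	.
Id/g	I	Id/g	I	Myosin_head-IQ-Myosin_TH1	.	.
Ik	I	Ik	I	Myosin_head-IQ-Myosin_TH1	.	unicellular-holozoan subclass
If	I	If	If	Myosin_head-Myosin_TH1-SH3_1	.	TH1 tail with C-terminal SH3
II	II	.	II	Myosin_N-Myosin_head-IQ-Myosin_tail_1	.	class-level unit; coiled-coil tail
II_striated	II	striated	II	Myosin_N-Myosin_head-IQ-Myosin_tail_1	.	striated-muscle subclass; extra 29-aa coiled-coil repeat
II_smooth	II	smooth	II	Myosin_N-Myosin_head-IQ-Myosin_tail_1	.	smooth/nonmuscle subclass
III	III	.	MyTH4-FERM	Pkinase-Myosin_head-IQ	.	N-terminal kinase
III-like	III-like	.	MyTH4-FERM	Pkinase-Myosin_head-IQ	.	expanded holozoan group; very variable tails
IV	IV	.	IV	Myosin_head-WW-MyTH4	Myosin_head-WW-MyTH4-SH3_1	WW either N- or C-terminal of the head
V	V	.	V-like	Myosin_head-IQ-DIL	.	.
Vp	Vp	.	V-like	Myosin_head-IQ-DIL	.	.
VI	VI	.	VI	Myosin_N-Myosin_head	.	minus-end directed
VII	VII	.	MyTH4-FERM	Myosin_head-IQ-MyTH4-FERM-SH3_1-MyTH4-FERM	.	tandem MyTH4-FERM
VIII	VIII	.	VIII	Myosin_head-IQ	.	green-lineage class
IX	IX	.	MyTH4-FERM	RA-Myosin_head-IQ-C1_1-RhoGAP	.	.
X	X	.	MyTH4-FERM	Myosin_head-IQ-PH(x2)-MyTH4-FERM	.	.
XI	XI	.	V-like	Myosin_head-IQ-DIL	.	green-lineage class
XIII	XIII	.	XIII	Myosin_head-IQ	.	kinetoplastid+heterolobosean class
XIV	XIV	.	XIV	Myosin_head	Myosin_head-MyTH4-FERM	alveolate class; ciliate members carry MyTH4-FERM tails
XV	XV	.	MyTH4-FERM	Myosin_head-MyTH4-FERM-SH3_1-MyTH4	.	.
XVI	XVI	.	MyTH4-FERM	Ank_2-Myosin_head	Myosin_head-Chitin_synth_2	annelid/mollusc members carry a chitin-synthase tail
XVII	XVII	.	MyTH4-FERM	Myosin_head-Cyt_b5-Chitin_synth_2-DEK_C	.	chitin-synthase myosin
XVIII	XVIII	.	XVIII	PDZ-Myosin_head-Myosin_tail_1	.	.
XIX	XIX	.	V-like	Myosin_head-IQ	.	.
XX	XX	.	MyTH4-FERM	Myosin_head-IQ	.	.
XXI	XXI	.	V-like	Myosin_head-IQ	Myosin_head-WW;Myosin_head-PX;Myosin_head-Tub	diverse heterokont tails
XXII	XXII	.	MyTH4-FERM	Myosin_head-IQ-MyTH4-RA-FERM-MyTH4-FERM	.	RA between first MyTH4 and first FERM
XXIII	XXIII	.	XXIII	Myosin_head-IQ	.	alveolate class
XXV	XXV	.	MyTH4-FERM	Myosin_head-MyTH4-FERM	.	amoebozoan; formerly called VII
XXVI	XXVI	.	MyTH4-FERM	Myosin_head-MyTH4-FERM	.	amoebozoan
XXVII	XXVII	.	V-like	Myosin_head-IQ	.	heterokont+alveolate class
XXX	XXX	.	XXX	Myosin_head-PH	Myosin_head-PX	.
XXXI	XXXI	.	XXXI	Myosin_head-IQ-Ank_2-PH-Ank_2-Aida_C2	.	.
XXXIII	XXXIII	.	V-like	Myosin_head-IQ-DIL	.	amoebozoan; formerly called V
XXXIV	XXXIV	.	MyTH4-FERM	Myosin_head-MyTH4	.	.
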