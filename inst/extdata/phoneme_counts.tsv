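language	phoneme	manner	count
korean	YEO	vowel	150
korean	WO	vowel	100
korean	A	vowel	1000
korean	E	vowel	400
korean	I	vowel	750
korean	EO	vowel	500
korean	YO	vowel	200
korean	U	vowel	450
korean	EU	vowel	750
korean	AE	vowel	150
korean	O	vowel	100
korean	HA	vowel	100
korean	WA	vowel	50
korean	N	nasal	1150
korean	NG	nasal	300
korean	M	nasal	300
korean	L	nasal	450
korean	B	plosive	200
korean	P	plosive	450
korean	K	plosive	500
korean	KK	plosive	300
korean	D	plosive	100
korean	T	plosive	50
korean	SS	fricative	100
korean	S	fricative	500
korean	H	fricative	200
korean	J	fricative	550
korean	CH	fricative	150
english	AA	vowel	300
english	AO	vowel	100
english	AH	vowel	700
english	AW	vowel	150
english	OW	vowel	150
english	AR	vowel	500
english	EY	vowel	200
english	AY	vowel	300
english	EH	vowel	150
english	UW	vowel	100
english	IY	vowel	150
english	IH	vowel	500
english	ER	vowel	350
english	UH	vowel	150
english	M	nasal	400
english	L	nasal	400
english	N	nasal	550
english	NG	nasal	200
english	R	nasal	200
english	Y	plosive	50
english	W	plosive	200
english	B	plosive	300
english	P	plosive	300
english	G	plosive	150
english	T	plosive	850
english	D	plosive	350
english	K	plosive	500
english	V	plosive	50
english	DH	fricative	400
english	CH	fricative	150
english	Z	fricative	200
english	S	fricative	600
english	HH	fricative	100
english	F	fricative	50
english	SH	fricative	100
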