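gene	mutation	fitness_score	antibiotic
soxR	G121K	14.21059826	Doxycycline
soxR	I120E	13.41328904	Doxycycline
soxR	G121N	12.61816091	Doxycycline
soxR	G121P	10.68028162	Doxycycline
soxR	G121I	9.176806682	Doxycycline
soxR	I120D	2.9096309542	Doxycycline
soxR	I120E	1.3365831269	Thiamphenicol
crp	V140W	11.1088135691	Gentamicin
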