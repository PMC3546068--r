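site	experiment	condition	normalized_area
Ser29	1	control	1.10E-05
Ser29	2	control	1.20E-05
Ser29	3	control	2.85E-05
Ser29	4	control	5.18E-05
Ser29	1	treated	3.89E-05
Ser29	2	treated	6.84E-05
Ser29	3	treated	5.64E-05
Ser29	4	treated	1.48E-04
Ser504	1	control	2.12E-06
Ser504	2	control	2.53E-05
Ser504	3	control	1.06E-05
Ser504	4	control	0.00E+00
Ser504	1	treated	7.66E-05
Ser504	2	treated	1.85E-04
Ser504	3	treated	1.39E-04
Ser504	4	treated	4.33E-05
Ser645/T646	1	control	1.50E-04
Ser645/T646	2	control	2.93E-04
Ser645/T646	3	control	3.01E-04
Ser645/T646	4	control	4.04E-04
Ser645/T646	1	treated	3.00E-04
Ser645/T646	2	treated	5.89E-04
Ser645/T646	3	treated	7.03E-04
Ser645/T646	4	treated	1.10E-03
Ser711	1	control	4.15E-05
Ser711	2	control	5.58E-05
Ser711	3	control	7.55E-05
Ser711	4	control	1.22E-04
Ser711	1	treated	4.29E-05
Ser711	2	treated	2.36E-05
Ser711	3	treated	8.23E-05
Ser711	4	treated	6.52E-05
Ser760	1	control	3.43E-05
Ser760	2	control	3.59E-05
Ser760	3	control	2.84E-05
Ser760	4	control	3.89E-05
Ser760	1	treated	2.13E-05
Ser760	2	treated	2.85E-05
Ser760	3	treated	2.83E-05
Ser760	4	treated	2.08E-05
Ser839	1	control	1.36E-05
Ser839	2	control	2.74E-05
Ser839	3	control	3.23E-05
Ser839	4	control	2.61E-04
Ser839	1	treated	1.67E-05
Ser839	2	treated	5.48E-05
Ser839	3	treated	0.00E+00
Ser839	4	treated	2.70E-04
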