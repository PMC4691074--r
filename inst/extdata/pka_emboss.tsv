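group	pka	charge
Nterm	8.60	basic
Cterm	3.60	acidic
D	3.90	acidic
E	4.10	acidic
C	8.50	acidic
Y	10.10	acidic
H	6.50	basic
K	10.80	basic
R	12.50	basic
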