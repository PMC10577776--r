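tautomer	mode	mode_class	dc_scivr	scaled_harmonic	experimental
K9K-1	Gua NH str in NH2	NH	3620	3538	3603
K9K-1	Cyt NH str in NH2	NH	3574	3526	3545
K9K-1	Gua N9H str	NH	3529	3505	alkylated
K9K-1	Cyt NH str	NH	3504	3476	alkylated
K9K-1	Gua NH str in NH2 (H-bonded)	NH	3368	3343	3283
K7E-1	Cyt OH str	OH	3656	3595	3615
K7E-1	Gua NH2 a.str	NH	3534	3547	3520
K7E-1	Cyt NH2 a.str	NH	3559	3531	3561
K7E-1	Gua N7H str	NH	3536	3511	3543
K7E-1	Gua NH2 s.str	NH	3448	3419	3436
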