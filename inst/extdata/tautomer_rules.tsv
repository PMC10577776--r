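label	window_lo	window_hi	requirement	min_fwhm	max_fwhm
K7E-1-like	3416	3456	present	NA	60
K7E-1-like	3250	3310	absent	60	NA
K9K-1-like	3250	3310	present	60	NA
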