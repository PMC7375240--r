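# Michael-acceptor warhead patterns, one per line, in priority order.
# A match is a non-ring C=C whose alpha carbon bonds an electron-withdrawing
# group (EWG) atom of element ewg_element carrying n_double_o double-bonded
# oxygens; x_element is the element of the EWG substituent that distinguishes
# the class (e.g. amide N vs ester O vs ketone C), and x_needs_carbon marks
# whether that substituent must itself bond a further carbon (ester-type
# oxygen). Rows are tried top to bottom; the first match at a site wins.
pattern_id	ewg_element	n_double_o	x_element	x_needs_carbon
acrylamide	C	1	N	FALSE
acrylate_ester	C	1	O	TRUE
enone	C	1	C	FALSE
vinyl_sulfonate	S	2	O	TRUE
vinyl_sulfone	S	2	C	FALSE
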