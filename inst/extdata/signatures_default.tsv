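signature_id	family	boxes	gap_min	gap_max	nterm	nterm_window
sig_des_d9a	DES_D9A	HRLWSH;HRXHH;HNXHH	15	300	none	150
sig_des_d4	DES_D4	HXXHH;HXXXHH;HXXXH	15	300	cytb5	150
sig_des_d5	DES_D5	HDXGH;HXXXHH|HXXHH;QIEHH	15	300	cytb5	150
sig_des_d6	DES_D6	HDXGH;HXXXHH|HXXHH;QLEHH	15	300	cytb5	150
sig_des_d8	DES_D8	HDXGH;HXXXHH|HXXHH;QVEHH	15	300	cytb5	150
sig_des_w6d9b	DES_w6D9B	H[ED]CGH;HXXHH;HVXHH	15	300	DUF3474	150
sig_des_w3	DES_w3	HDCGH;HRYHH;HVAHH	15	300	none	150
sig_des_u1	DES_U1	HDXGH;HXXXHH|HXXHH;QAEHH	15	300	cytb5	150
sig_des_u2	DES_U2	HDXGH;HXXXHH|HXXHH;QGEHH	15	300	cytb5	150
sig_des_u3	DES_U3	HDXGH;HXXXHH|HXXHH;QSEHH	15	300	cytb5	700
sig_elo_c16	ELO_C16	HXXHH	15	300	none	150
sig_elo_c16l	ELO_C16L	HXXHH	15	300	none	150
sig_elo_c18	ELO_C18	HXXHH	15	300	none	150
sig_elo_c20	ELO_C20	QXXHH	15	300	none	150
sig_elo_d9	ELO_D9	HXXHH	15	300	none	150
sig_elo_u1	ELO_U1	HXXHH	15	300	none	150
sig_elo_u2	ELO_U2	HXXHH	15	300	none	150
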