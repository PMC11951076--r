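name	category	signature_id
PfaA	pufa_synthase	.
PfaB	pufa_synthase	.
PfaC	pufa_synthase	.
DES_D4	desaturase	sig_des_d4
DES_D5	desaturase	sig_des_d5
DES_D6	desaturase	sig_des_d6
DES_D8	desaturase	sig_des_d8
DES_D9A	desaturase	sig_des_d9a
DES_w6D9B	desaturase	sig_des_w6d9b
DES_w3	desaturase	sig_des_w3
DES_U1	desaturase	sig_des_u1
DES_U2	desaturase	sig_des_u2
DES_U3	desaturase	sig_des_u3
ELO_C16	elongase	sig_elo_c16
ELO_C16L	elongase	sig_elo_c16l
ELO_C18	elongase	sig_elo_c18
ELO_C20	elongase	sig_elo_c20
ELO_D9	elongase	sig_elo_d9
ELO_U1	elongase	sig_elo_u1
ELO_U2	elongase	sig_elo_u2
ACLY	accessory	.
cCrAT	accessory	.
CrtZ	accessory	.
CrtO	accessory	.
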