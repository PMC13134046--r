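id	name	equation	gpr	subsystem
LYSAM	Lysine 2,3-aminomutase	lys_c -> blys_c	WP_009258627_1	Lysine degradation
DH36M	Lysine 5,6-aminomutase	blys_c -> dahx_c	WP_009258626_1 and WP_007493054_1	Lysine degradation
DH35O	3,5-diaminohexanoate dehydrogenase	dahx_c + nad_c -> kahx_c + nadh_c + nh4_c	WP_007493057_1	Lysine degradation
A53C	3-keto-5-aminohexanoate cleavage	kahx_c + accoa_c -> abcoa_c + acac_c	WP_007493059_1	Lysine degradation
AB3CL	3-aminobutyryl-CoA ammonia lyase	abcoa_c -> crcoa_c + nh4_c	WP_009259558_1 or WP_007488193_1	Lysine degradation
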