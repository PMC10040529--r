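strain_id	max_nacl_percent
KCTC_42006	10
JCM_17802	9
KCTC_12311	9
KCTC_52763	5
KCTC_42453	4
KCTC_52259	3
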