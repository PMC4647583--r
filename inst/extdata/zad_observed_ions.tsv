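# High-resolution positive-mode ions observed for zooxanthellamide D
# (neutral formula C54H83NO19), printed at 4 decimal places.
ion	mz
[M+H]+	1050.5657
[M+NH4]+	1067.5922
[M+Na]+	1072.5476
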