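# Secondary metabolites reported from Symbiodinium spp. with their
# reported m/z values, for screening observed polyhydroxy ions.
name	reported_mz
Neosymbioimine	404.154
Norcarothenoids	630.3557
Symbiodinolide	2859
Symbioimine	378.1368
Symbioramide	582
Symbiospirols	1229
Zooxanthellatoxin A	2872
Zooxanthellatoxin B	2829.9
Zooxanthellamide A	2715.4
Zooxanthellamide B	2697.4
Zooxanthellamide C	2697.4016
Zooxanthellamide D	1072.6
Zooxanthellamine	498.321
Zooxanthellactone	327.2317
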