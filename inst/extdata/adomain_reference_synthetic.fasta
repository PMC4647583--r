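>Adom_ref_synthetic synthetic GrsA-type A-domain stand-in; pocket code DAWTIAAI
VLYAEEGTETYGHLMGGGYCFSWYTFRHEYMIAQWRWMKPDWMNTTSEMGWQWEQLKFRW
QPCLWDNQSSPHIQPQSCTFHKSCKDCECCAYANPSLDAHWTPELFHTHMNQQFSTQLTH
CAHRASMVATDEEKNQKTMKPHNNSRYNKVNCAIHCKNLFATPTDVQNRLGWLISFQIPS
YFQFSFGMLSKTKAVTLLNCRITIAMAMFYCFDYRMIERRYEFHRIAARWNDIRDAWMWE
DKMACLIAGSGMVIMKRPPDDEEKWIKAMLKKGCDFCTPNGHETFECYNEKSRQAFFPIF
AAVGQQYKQCPKMYKRTWAATAGRVIAWTINSCKAGCRECMMSYRLISLYVCHKMAWSNS
QFIGDVYATSSEFIHVCGIYGPYDNVWPTLSYIFRMPMPDYAWEPPHWVFGHWNTHIPHI
NRVDDCQTDGWYPTKSMYRRKECRQWPENT
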