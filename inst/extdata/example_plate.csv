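well,sample_id,assay_id,experiment_id,is_ntc,exclusion_flags,acgh_cn
A01,S1,exon_VIII,E1,FALSE,,6
A02,S2,exon_VIII,E1,FALSE,wga,8
H12,,,,TRUE,,
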