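class,segments_per_subject,frames
pain,1,50250
other,3,147532
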