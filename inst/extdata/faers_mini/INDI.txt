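primaryid$indi_pt
CASE001.1$hereditary hypophosphataemic rickets
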