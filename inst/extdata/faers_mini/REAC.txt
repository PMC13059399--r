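primaryid$pt
CASE001.1$injection site pain
CASE001.1$pyrexia
CASE002.1$nephrocalcinosis
CASE003.2$headache
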