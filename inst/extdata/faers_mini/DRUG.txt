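primaryid$drugname$role_cod
CASE001.1$CRYSVITA$PS
CASE001.1$calcitriol$C
CASE002.1$burosumab$PS
CASE003.2$paracetamol$PS
CASE003.2$Burosumab$SS
CASE004.1$burosumab$PS
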