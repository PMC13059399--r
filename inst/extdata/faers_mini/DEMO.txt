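primaryid$caseid$caseversion$fda_dt$sex$age_grp$occr_country
CASE001.1$CASE001$1$20180215$F$LT18$United States
CASE002.1$CASE002$1$20190701$UNK$UNK$UNK
CASE003.2$CASE003$2$20240901$M$GE18$United Kingdom
CASE004.1$CASE004$1$20200401$UNK$UNK$UNK
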