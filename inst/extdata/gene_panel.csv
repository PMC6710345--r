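gene,class,subclass
16S,16S,ribosomal
copA,MRG,copper
copB,MRG,copper
pcoA,MRG,copper
czcA,MRG,multimetal
czcC,MRG,multimetal
czcD,MRG,multimetal
arsB,MRG,arsenic
arsC,MRG,arsenic
pbrT,MRG,lead
chrB,MRG,chromium
tetA,ARG,tetracycline
tetC,ARG,tetracycline
tetG,ARG,tetracycline
tetK,ARG,tetracycline
tetM,ARG,tetracycline
tetO,ARG,tetracycline
tetQ,ARG,tetracycline
tetS,ARG,tetracycline
tetW,ARG,tetracycline
tetX,ARG,tetracycline
tetA/P,ARG,tetracycline
tetB/P,ARG,tetracycline
sulII,ARG,sulfonamide
ereA,ARG,macrolide
mphA,ARG,macrolide
blaCTX-M,ARG,beta-lactam
blaSHV,ARG,beta-lactam
intI1,MGE,integron
tnpA,MGE,transposase
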