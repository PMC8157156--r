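actual,PDO,I,FI
PDO,1881,918,3
I,850,440,3
FI,4,2,0
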