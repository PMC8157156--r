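actual,PDO,I,FI
PDO,2408,419,1
I,909,306,1
FI,0,0,0
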