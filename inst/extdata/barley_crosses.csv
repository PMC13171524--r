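cross_id,parent1,parent2,mean,seg_var
ETIx146,ETI,146,82.85,8.73
ETIxANT,ETI,ANT,94.23,1.46
ETIxD33,ETI,D33,87.10,5.23
ETIxD37,ETI,D37,83.53,11.91
JENx146,JEN,146,85.88,11.65
JENxANT,JEN,ANT,97.26,1.04
JENxD33,JEN,D33,90.13,7.32
JENxD37,JEN,D37,86.56,15.17
MERx146,MER,146,85.08,12.12
MERxANT,MER,ANT,96.45,1.20
MERxD33,MER,D33,89.33,6.36
MERxD37,MER,D37,85.75,12.75
OTTx146,OTT,146,82.95,9.83
OTTxANT,OTT,ANT,94.33,0.96
OTTxD33,OTT,D33,87.20,3.68
OTTxD37,OTT,D37,83.63,10.06
QUAx146,QUA,146,85.93,11.74
QUAxANT,QUA,ANT,97.31,1.05
QUAxD33,QUA,D33,90.18,7.37
QUAxD37,QUA,D37,86.61,15.20
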