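cohort,characteristic,level,mutant,wildtype
training,counts,all,171,97
validation,counts,all,80,35
test,counts,all,39,16
training,gender,male,59,54
training,gender,female,112,43
training,smoking,no,132,51
training,smoking,yes,39,46
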