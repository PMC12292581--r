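method,after_task,task1,task2,task3,task4
Finetune,1,97.76,NA,NA,NA
Finetune,2,0,82.22,NA,NA
Finetune,3,0,0,94.59,NA
Finetune,4,0,0,0,82.88
SI,1,94.46,NA,NA,NA
SI,2,0,84.79,NA,NA
SI,3,0,0,90.23,NA
SI,4,0,0,0,83.92
ER,1,97.66,NA,NA,NA
ER,2,1.98,77.34,NA,NA
ER,3,0.6,0.78,90.49,NA
ER,4,0,0,0,82.51
DER,1,98.81,NA,NA,NA
DER,2,41.81,95.09,NA,NA
DER,3,20.82,63.73,89.84,NA
DER,4,13.05,51.34,17.71,82.29
AGEM,1,97.93,NA,NA,NA
AGEM,2,96.51,0,NA,NA
AGEM,3,2.48,21.32,88.41,NA
AGEM,4,4.64,25.45,18.88,82.90
DSCNL,1,99.95,NA,NA,NA
DSCNL,2,97.84,97.32,NA,NA
DSCNL,3,63.79,77.46,93.03,NA
DSCNL,4,72.70,73.10,18.82,90.32
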