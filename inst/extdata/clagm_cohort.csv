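patient_id,group,os_months,event,response
A1,A,131,FALSE,CR
A2,A,15,FALSE,CRh
A3,A,8,TRUE,CRh
A4,A,9,TRUE,CRh
A5,A,10,TRUE,CR
A6,A,6,TRUE,CR
A7,A,3,FALSE,PR
A8,A,5,FALSE,PR
B1,B,28,TRUE,CR
B2,B,23,TRUE,CR
B3,B,23,TRUE,CR
B4,B,2,TRUE,REFRACTORY
B5,B,11,FALSE,REFRACTORY
B6,B,23,FALSE,CR
B7,B,9,TRUE,REFRACTORY
B8,B,20,TRUE,REFRACTORY
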