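patient_id,day,psa_ng_ml,pet_negative
P1,0,3.4,FALSE
P1,7,4.2,FALSE
P1,21,3.5,FALSE
P1,28,3.5,FALSE
P2,0,5.2,TRUE
P2,7,4.4,TRUE
P2,21,2.5,TRUE
P2,28,2.0,TRUE
P3,0,0.9,FALSE
P3,7,,FALSE
P3,21,,FALSE
P3,28,0.1,FALSE
P4,0,59.0,FALSE
P4,7,35.0,FALSE
P4,21,8.4,FALSE
P4,28,6.9,FALSE
P5,0,17.0,FALSE
P5,7,13.0,FALSE
P5,21,11.0,FALSE
P5,28,14.0,FALSE
P6,0,9.0,FALSE
P6,7,7.0,FALSE
P6,21,4.0,FALSE
P6,28,0.8,FALSE
P7,0,27.0,FALSE
P7,7,,FALSE
P7,21,,FALSE
P7,28,2.7,FALSE
P8,0,30.0,FALSE
P8,7,17.0,FALSE
P8,21,13.0,FALSE
P8,28,11.0,FALSE
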