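patient,age,gender,instrument,symptomatic_digits,duration_years,severity
P01,39,male,piano,R-D1,2,3
P02,49,male,piano,R-D1;L-D1,5,2
P03,56,male,guitar,R-D2,9,2
P04,49,male,piano,R-D3;R-D4;L-D1,7,3
P05,68,male,piano,R-D4;R-D5,26,2
P06,51,male,guitar,R-D1;R-D2,6,2
P07,51,female,guitar,R-D2;R-D3;R-D4,3,2
P08,39,male,guitar,R-D3,2,3
P09,47,male,piano,R-D4;R-D5,4,4
P10,51,male,guitar,R-D3;R-D4,6,3
P11,49,male,guitar,R-D1,16,2
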