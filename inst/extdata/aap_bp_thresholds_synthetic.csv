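sex,age,height,sbp_p90,dbp_p90,sbp_p95,dbp_p95
female,4,95,101,63,105,67
female,4,105,103,65,107,69
female,5,102,102,64,106,68
female,5,112,104,66,108,70
female,6,108,103,65,107,69
female,6,118,105,67,109,71
female,7,113,104,66,108,70
female,7,123,106,68,110,72
female,8,118,105,67,109,71
female,8,128,107,69,111,73
female,9,123,107,68,111,72
female,9,133,109,70,113,74
female,10,128,109,70,113,74
female,10,140,111,72,115,76
male,4,96,102,62,106,66
male,4,106,104,64,108,68
male,5,103,103,63,107,67
male,5,113,105,65,109,69
male,6,109,104,64,108,68
male,6,119,106,66,110,70
male,7,114,105,65,109,69
male,7,124,107,67,111,71
male,8,119,106,66,110,70
male,8,129,108,68,112,72
male,9,124,108,67,112,71
male,9,134,110,69,114,73
male,10,129,110,69,114,73
male,10,141,112,71,116,75
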