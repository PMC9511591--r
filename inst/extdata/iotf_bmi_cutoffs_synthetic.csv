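sex,age,underweight,overweight,obese
female,4,14.0,17.2,19.1
female,5,13.9,17.1,19.2
female,6,13.8,17.3,19.7
female,7,13.9,17.8,20.5
female,8,14.0,18.3,21.6
female,9,14.3,19.1,22.8
female,10,14.6,19.9,24.1
male,4,14.2,17.6,19.3
male,5,14.1,17.4,19.3
male,6,14.0,17.6,19.8
male,7,14.0,17.9,20.6
male,8,14.1,18.4,21.6
male,9,14.3,19.1,22.8
male,10,14.6,19.8,24.0
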