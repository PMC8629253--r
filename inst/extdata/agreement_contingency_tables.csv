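sample,A,B,C,D
student,675,209,13,13000
adult1,464,306,11,4549
adult2,457,35,27,2626
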