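T_celsius,lambda,vhc_MJ,sigma
5,0.409,3.339,1.228
25,0.451,3.383,1.991
45,0.490,3.441,2.756
65,0.532,3.496,3.514
85,0.571,3.589,4.278
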