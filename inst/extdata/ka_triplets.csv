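compound,wt,bcrp_ko,pgp_ko
ciprofloxacin,1.63,1.85,2.18
nitrofurantoin,5.80,6.89,7.20
topotecan,3.18,5.18,3.68
sulfasalazine,1.40,0.49,0.93
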