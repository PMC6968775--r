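compound,wt,bcrp_ko,pgp_ko
ciprofloxacin,0.47,0.51,0.75
nitrofurantoin,0.64,0.77,0.75
topotecan,0.57,1.03,0.64
sulfasalazine,0.16,1.30,0.30
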