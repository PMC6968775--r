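compound,r_bcrp,r_pgp
ciprofloxacin,0.05,0.36
nitrofurantoin,0.15,0.13
topotecan,0.42,0.06
sulfasalazine,0.79,0.09
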