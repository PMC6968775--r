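compound,aq_bcrp,aq_pgp
ciprofloxacin,0.03,0.13
nitrofurantoin,0.37,0.09
topotecan,0.61,0.14
sulfasalazine,0.59,0.05
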