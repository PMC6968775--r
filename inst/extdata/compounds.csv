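name,mw_dosed,rb,dose_iv,dose_oral
ciprofloxacin,331.34,1.20,1,1
nitrofurantoin,238.16,1.18,1,2
topotecan,457.9,0.94,1,1
sulfasalazine,398.39,1.28,1,5
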