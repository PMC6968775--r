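compound,genotype,auc_iv,auc_pv,auc_sys
ciprofloxacin,WT,886,489,306
ciprofloxacin,BcrpKO,1200,564,365
ciprofloxacin,Mdr1a1bKO,1290,896,601
nitrofurantoin,WT,1840,2550,1840
nitrofurantoin,BcrpKO,1840,3410,2560
nitrofurantoin,Mdr1a1bKO,1950,3180,2350
topotecan,WT,994,577,370
topotecan,BcrpKO,1490,1510,1140
topotecan,Mdr1a1bKO,1020,589,358
sulfasalazine,WT,3820,2200,1940
sulfasalazine,BcrpKO,60500,290000,288000
sulfasalazine,Mdr1a1bKO,4280,2770,2450
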