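date,droppings_collected,samples_genotyped,individuals,visual_count,sex_ratio
2012-05-22,50,43,41,400,0.03
2012-06-20,50,36,31,360,0.04
2012-07-10,50,45,43,230,0.05
2012-08-03,50,44,41,240,0.03
2012-08-29,50,42,28,40,0.27
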