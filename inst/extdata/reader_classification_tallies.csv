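mode,reader,method,progressive,stable,regressive,discrepant_vs_reference
absolute,1,quantitative,13,13,26,NA
absolute,1,planar,15,21,16,18
absolute,1,spectct,11,16,25,11
absolute,2,quantitative,12,15,25,NA
absolute,2,planar,20,12,20,22
absolute,2,spectct,18,12,22,14
ratio,1,quantitative,12,20,14,NA
ratio,1,planar,14,18,14,14
ratio,1,spectct,10,15,21,16
ratio,2,quantitative,10,22,14,NA
ratio,2,planar,19,9,18,23
ratio,2,spectct,18,8,20,19
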