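id,metric,value
baseline,params_million,3.02
baseline,flops_g,8.1
baseline,size_mb,6
esppf,params_million,2.86
esppf,flops_g,8.0
esppf+ehconv,params_million,2.30
esppf+ehconv,flops_g,6.9
esppf+rc2f,params_million,2.27
esppf+rc2f,flops_g,7.0
esppf+pfdetect,params_million,2.16
esppf+pfdetect,flops_g,5.4
esppf+ehconv+rc2f,params_million,1.71
esppf+ehconv+rc2f,flops_g,5.9
esppf+ehconv+pfdetect,params_million,1.60
esppf+ehconv+pfdetect,flops_g,4.3
esppf+rc2f+pfdetect,params_million,1.57
esppf+rc2f+pfdetect,flops_g,4.4
pfl,params_million,1.01
pfl,flops_g,3.3
pfl,size_mb,2.1
head_baseline,params,762244
head_baseline,flops_g,3.025
head_pfl,params,59861
head_pfl,flops_g,0.405
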