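# Published posterior summaries (stage-2, scenario 6b) for the European
# walnut demographic analysis: effective sizes (diploid individuals),
# event times (generations) and admixture rates. Used by the analysis
# drivers to convert coalescent generations to calendar years BP.
param,description,mean,median,q05,q95
N1,effective size of pool1 (Anatolia),5620,5460,2090,9380
N2,effective size of pool2 (Balkans),3220,2550,700,8270
N3,effective size of pool3 (northeastern Europe),6300,6460,2170,9690
N4,effective size of pool4 (western Europe),6140,6320,2550,9120
Nm,size of pool4 before its decline at tm,7730,8040,4610,9860
Nd,size of pool3 before its expansion at td,1440,972,214,4320
NG1,size of the ancestral Balkan pool,2140,1620,440,6260
NAnc,size of the ancestor of pool1 and NG1,5940,6210,1610,9440
tm,time of the western European decline,2.86,1.96,1,10
td,time of the northeastern European expansion,6.03,5.23,1,13.8
t1,time of the admixture founding pool3,19.2,19.7,11.9,25
t2,time of the admixture founding pool2,48.5,51.3,28.6,59.7
t3,divergence of pool4 from NG1,118,118,42.3,192
t4,divergence of pool1 from NG1,800,579,217,2010
ra,admixture rate (pool1 side) at t2,0.262,0.258,0.14,0.39
rb,admixture rate (pool4 side) at t1,0.395,0.381,0.153,0.681
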