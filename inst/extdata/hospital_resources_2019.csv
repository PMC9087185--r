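tier,hospitals,certified_doctors,beds,visits_10k
FLH,11264,135471,651045,22965
SLH,9687,720121,2665974,134343
TLH,2749,1030988,2777932,205701
Total,23700,1886580,6094951,363009
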