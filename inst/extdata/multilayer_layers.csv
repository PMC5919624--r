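layer,surface_area_mm2,volume_mm3,dgi_1mm_mm,dgi_2mm_mm,dgi_3mm_mm
0,1477.332,4099.663,NA,NA,NA
1,1802.676,5778.131,1.023454,NA,NA
2,2154.435,7781.413,1.012497,2.027526,NA
3,2522.306,10106.71,0.994409,2.001663,3.003796
4,2920.762,12842.98,1.005416,1.994630,2.991402
5,3345.715,15992.61,1.005229,2.006092,2.985806
6,3789.611,19550.83,0.997355,1.999247,2.992473
7,4261.514,23565.85,0.997381,1.991066,2.985925
8,4768.102,28178.60,1.021692,2.016372,3.003763
9,5286.241,33161.19,0.991131,2.009966,2.999245
10,5829.997,38702.98,0.997063,1.986088,2.999972
11,6411.771,44898.54,1.012200,2.006726,2.991078
12,7006.067,51577.42,0.995523,2.005980,2.996383
13,7627.859,58884.88,0.998701,1.992409,2.999274
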