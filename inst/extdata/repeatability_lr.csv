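specimen,distance_label,technique,operator,replicate,value_mm
Ovalisia,L-R,uCT,B,1,5.48
Ovalisia,L-R,uCT,B,2,5.51
Ovalisia,L-R,uCT,B,3,5.51
Ovalisia,L-R,uCT,B,4,5.50
Ovalisia,L-R,uCT,B,5,5.50
Ovalisia,L-R,uCT,B,6,5.49
Ovalisia,L-R,uCT,B,7,5.49
Ovalisia,L-R,uCT,B,8,5.51
Ovalisia,L-R,uCT,B,9,5.51
Ovalisia,L-R,uCT,B,10,5.50
Ovalisia,L-R,uCT,B,11,5.48
Ovalisia,L-R,uCT,B,12,5.50
Ovalisia,L-R,uCT,B,13,5.48
Ovalisia,L-R,uCT,B,14,5.49
Ovalisia,L-R,uCT,B,15,5.49
Ovalisia,L-R,uCT,B,16,5.50
Ovalisia,L-R,uCT,B,17,5.48
Ovalisia,L-R,uCT,B,18,5.51
Ovalisia,L-R,uCT,B,19,5.49
Ovalisia,L-R,uCT,B,20,5.49
Ovalisia,L-R,SL,B,1,5.60
Ovalisia,L-R,SL,B,2,5.60
Ovalisia,L-R,SL,B,3,5.62
Ovalisia,L-R,SL,B,4,5.57
Ovalisia,L-R,SL,B,5,5.60
Ovalisia,L-R,SL,B,6,5.59
Ovalisia,L-R,SL,B,7,5.58
Ovalisia,L-R,SL,B,8,5.62
Ovalisia,L-R,SL,B,9,5.61
Ovalisia,L-R,SL,B,10,5.59
Ovalisia,L-R,SL,B,11,5.59
Ovalisia,L-R,SL,B,12,5.59
Ovalisia,L-R,SL,B,13,5.58
Ovalisia,L-R,SL,B,14,5.59
Ovalisia,L-R,SL,B,15,5.57
Ovalisia,L-R,SL,B,16,5.59
Ovalisia,L-R,SL,B,17,5.58
Ovalisia,L-R,SL,B,18,5.62
Ovalisia,L-R,SL,B,19,5.59
Ovalisia,L-R,SL,B,20,5.58
Ovalisia,L-R,SfM,B,1,5.46
Ovalisia,L-R,SfM,B,2,5.46
Ovalisia,L-R,SfM,B,3,5.48
Ovalisia,L-R,SfM,B,4,5.48
Ovalisia,L-R,SfM,B,5,5.48
Ovalisia,L-R,SfM,B,6,5.48
Ovalisia,L-R,SfM,B,7,5.46
Ovalisia,L-R,SfM,B,8,5.47
Ovalisia,L-R,SfM,B,9,5.46
Ovalisia,L-R,SfM,B,10,5.46
Ovalisia,L-R,SfM,B,11,5.46
Ovalisia,L-R,SfM,B,12,5.47
Ovalisia,L-R,SfM,B,13,5.47
Ovalisia,L-R,SfM,B,14,5.47
Ovalisia,L-R,SfM,B,15,5.47
Ovalisia,L-R,SfM,B,16,5.47
Ovalisia,L-R,SfM,B,17,5.46
Ovalisia,L-R,SfM,B,18,5.48
Ovalisia,L-R,SfM,B,19,5.47
Ovalisia,L-R,SfM,B,20,5.47
Ovalisia,L-R,multiview,B,1,5.50
Ovalisia,L-R,multiview,B,2,5.50
Ovalisia,L-R,multiview,B,3,5.52
Ovalisia,L-R,multiview,B,4,5.52
Ovalisia,L-R,multiview,B,5,5.51
Ovalisia,L-R,multiview,B,6,5.50
Ovalisia,L-R,multiview,B,7,5.51
Ovalisia,L-R,multiview,B,8,5.49
Ovalisia,L-R,multiview,B,9,5.52
Ovalisia,L-R,multiview,B,10,5.51
Ovalisia,L-R,multiview,B,11,5.51
Ovalisia,L-R,multiview,B,12,5.50
Ovalisia,L-R,multiview,B,13,5.55
Ovalisia,L-R,multiview,B,14,5.53
Ovalisia,L-R,multiview,B,15,5.51
Ovalisia,L-R,multiview,B,16,5.51
Ovalisia,L-R,multiview,B,17,5.52
Ovalisia,L-R,multiview,B,18,5.53
Ovalisia,L-R,multiview,B,19,5.54
Ovalisia,L-R,multiview,B,20,5.49
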