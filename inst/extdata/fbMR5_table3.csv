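series,generation,location,crosses,pollinated_flowers,fruits,seeds,sown,scab_eliminated,pre_mas_losses,mas_tested,rgene_carriers,selected_for_lift,parents_next_gen
FB_MR5,pBC1,field,3,1129,242,1100,1098,353,134,611,332,135,9
FB_MR5,pBC2,field,10,1452,288,1809,1491,183,626,682,304,142,27
FB_MR5,pBC3,field,6,1006,182,960,960,124,228,608,304,13,4
FB_MR5,pBC4,field,5,1110,118,602,602,144,127,331,170,116,0
FB_MR5,pBC5,field,3,1107,333,800,800,301,207,292,137,50,5
FB_MR5,pBC6,field,2,373,55,197,13,0,2,11,3,3,0
FB_MR5,pBC1,LIFT,0,0,0,0,0,0,0,0,0,0,0
FB_MR5,pBC2,LIFT,1,15,10,59,59,0,38,21,10,8,1
FB_MR5,pBC3,LIFT,51,545,84,407,407,0,123,284,139,110,20
FB_MR5,pBC4,LIFT,33,715,85,559,559,0,81,478,217,123,3
FB_MR5,pBC5,LIFT,3,43,0,0,0,0,0,0,0,0,0
FB_MR5,pBC6,LIFT,10,188,5,36,36,0,12,24,11,11,0
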