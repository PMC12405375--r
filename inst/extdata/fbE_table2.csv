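series,generation,location,crosses,pollinated_flowers,fruits,seeds,sown,scab_eliminated,pre_mas_losses,mas_tested,rgene_carriers,selected_for_lift,parents_next_gen
Fb_E,F1,field,2,1288,227,977,977,3,395,579,279,57,16
Fb_E,pBC1,field,7,992,77,279,279,0,31,248,92,81,6
Fb_E,pBC2,field,5,1329,98,574,518,72,272,174,105,21,9
Fb_E,pBC3,field,2,134,21,119,119,10,92,17,6,0,0
Fb_E,pBC4,field,4,1068,231,1284,731,115,242,374,167,75,2
Fb_E,pBC5,field,0,0,0,0,0,0,0,0,0,0,0
Fb_E,F1,LIFT,0,0,0,0,0,0,0,0,0,0,0
Fb_E,pBC1,LIFT,13,328,119,507,287,0,125,162,49,40,2
Fb_E,pBC2,LIFT,14,247,41,218,157,0,84,73,39,30,11
Fb_E,pBC3,LIFT,34,457,88,572,572,0,220,352,181,129,13
Fb_E,pBC4,LIFT,32,707,64,472,472,11,97,364,194,92,0
Fb_E,pBC5,LIFT,3,74,7,31,31,0,4,27,14,10,0
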