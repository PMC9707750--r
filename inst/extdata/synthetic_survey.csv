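"method","reef_zone","site","area","species","total_length","count"
"clove_oil_station","back","site1",4,"goby_A",1.3,1
"clove_oil_station","back","site1",4,"goby_A",2.7,5
"clove_oil_station","back","site1",4,"goby_B",4,3
"clove_oil_station","back","site1",4,"goby_B",4.5,1
"clove_oil_station","back","site1",4,"goby_B",1.8,3
"clove_oil_station","back","site1",4,"blenny_A",5,4
"clove_oil_station","back","site1",4,"blenny_A",4.4,3
"clove_oil_station","back","site1",4,"blenny_A",2.2,4
"transect_30x5_benthic","back","site1",150,"cardinal_A",4.2,6
"transect_30x5_benthic","back","site1",150,"cardinal_A",5.1,5
"transect_30x5_benthic","back","site1",150,"damsel_A",8.9,3
"transect_30x5_benthic","back","site1",150,"damsel_A",6.6,5
"transect_30x5_benthic","back","site1",150,"damsel_A",3.7,4
"transect_30x5_benthic","back","site1",150,"damsel_B",3,4
"transect_30x5_benthic","back","site1",150,"damsel_B",6,2
"transect_30x5_benthic","back","site1",150,"damsel_B",5.1,2
"transect_30x5_benthic","back","site1",150,"wrasse_A",17,1
"transect_30x5_benthic","back","site1",150,"wrasse_A",18,3
"clove_oil_station","back","site1",4,"dottyback_A",4,3
"clove_oil_station","back","site1",4,"dottyback_A",4.6,2
"clove_oil_station","back","site1",4,"dottyback_A",3.6,4
"transect_50x5","back","site1",250,"grouper_A",14.4,6
"transect_50x5","back","site1",250,"grouper_A",16.3,1
"transect_50x5","back","site1",250,"grouper_A",4.7,4
"transect_30x5_benthic","back","site1",150,"hawkfish_A",7.7,1
"transect_30x5_benthic","back","site1",150,"hawkfish_A",20.8,6
"transect_30x5_benthic","back","site1",150,"hawkfish_A",9,1
"clove_oil_station","flat","site1",4,"goby_A",1.4,2
"clove_oil_station","flat","site1",4,"goby_A",1.1,5
"clove_oil_station","flat","site1",4,"goby_A",2.1,1
"clove_oil_station","flat","site1",4,"goby_B",7,4
"clove_oil_station","flat","site1",4,"goby_B",2.7,4
"clove_oil_station","flat","site1",4,"goby_B",4,2
"clove_oil_station","flat","site1",4,"blenny_A",2.3,4
"clove_oil_station","flat","site1",4,"blenny_A",1.9,1
"clove_oil_station","flat","site1",4,"blenny_A",3,4
"transect_30x5_benthic","flat","site1",150,"cardinal_A",3.8,1
"transect_30x5_benthic","flat","site1",150,"cardinal_A",4.9,6
"transect_30x5_benthic","flat","site1",150,"damsel_A",9.1,5
"transect_30x5_benthic","flat","site1",150,"damsel_A",7.9,6
"transect_30x5_benthic","flat","site1",150,"damsel_B",2.4,3
"transect_30x5_benthic","flat","site1",150,"damsel_B",5.6,4
"transect_30x5_benthic","flat","site1",150,"wrasse_A",12.7,4
"transect_30x5_benthic","flat","site1",150,"wrasse_A",19.2,5
"transect_30x5_benthic","flat","site1",150,"wrasse_A",18.7,2
"clove_oil_station","flat","site1",4,"dottyback_A",4.2,1
"clove_oil_station","flat","site1",4,"dottyback_A",3,5
"clove_oil_station","flat","site1",4,"dottyback_A",3.2,3
"transect_50x5","flat","site1",250,"grouper_A",20.4,1
"transect_50x5","flat","site1",250,"grouper_A",9.2,4
"transect_50x5","flat","site1",250,"grouper_A",9,5
"transect_30x5_benthic","flat","site1",150,"hawkfish_A",8.7,5
"transect_30x5_benthic","flat","site1",150,"hawkfish_A",9.4,2
"transect_30x5_benthic","flat","site1",150,"hawkfish_A",14.6,5
"clove_oil_station","crest","site1",4,"goby_A",2.8,1
"clove_oil_station","crest","site1",4,"goby_A",1.9,3
"clove_oil_station","crest","site1",4,"goby_B",3.4,3
"clove_oil_station","crest","site1",4,"goby_B",3.6,1
"clove_oil_station","crest","site1",4,"blenny_A",2.9,6
"clove_oil_station","crest","site1",4,"blenny_A",4.9,1
"clove_oil_station","crest","site1",4,"blenny_A",2.5,5
"transect_30x5_benthic","crest","site1",150,"cardinal_A",3.5,6
"transect_30x5_benthic","crest","site1",150,"cardinal_A",6.8,5
"transect_30x5_benthic","crest","site1",150,"damsel_A",3.9,5
"transect_30x5_benthic","crest","site1",150,"damsel_A",5.9,4
"transect_30x5_benthic","crest","site1",150,"damsel_A",4.7,4
"transect_30x5_benthic","crest","site1",150,"damsel_B",3.5,2
"transect_30x5_benthic","crest","site1",150,"damsel_B",4,2
"transect_30x5_benthic","crest","site1",150,"damsel_B",4,5
"transect_30x5_benthic","crest","site1",150,"wrasse_A",17.3,3
"transect_30x5_benthic","crest","site1",150,"wrasse_A",16.3,6
"clove_oil_station","crest","site1",4,"dottyback_A",3.1,3
"clove_oil_station","crest","site1",4,"dottyback_A",4.1,4
"transect_50x5","crest","site1",250,"grouper_A",15.8,6
"transect_50x5","crest","site1",250,"grouper_A",24.5,5
"transect_50x5","crest","site1",250,"grouper_A",10.3,4
"transect_30x5_benthic","crest","site1",150,"hawkfish_A",10.5,1
"transect_30x5_benthic","crest","site1",150,"hawkfish_A",9.7,5
"clove_oil_station","slope","site1",4,"goby_A",2.2,3
"clove_oil_station","slope","site1",4,"goby_A",4.1,2
"clove_oil_station","slope","site1",4,"goby_A",2.3,1
"clove_oil_station","slope","site1",4,"goby_B",2,1
"clove_oil_station","slope","site1",4,"goby_B",1.8,4
"clove_oil_station","slope","site1",4,"goby_B",2.9,4
"clove_oil_station","slope","site1",4,"blenny_A",3.8,5
"clove_oil_station","slope","site1",4,"blenny_A",5.9,6
"clove_oil_station","slope","site1",4,"blenny_A",1.5,6
"transect_30x5_benthic","slope","site1",150,"cardinal_A",4.3,5
"transect_30x5_benthic","slope","site1",150,"cardinal_A",2.7,4
"transect_30x5_benthic","slope","site1",150,"damsel_A",6.8,6
"transect_30x5_benthic","slope","site1",150,"damsel_A",3.6,3
"transect_30x5_benthic","slope","site1",150,"damsel_B",2.4,1
"transect_30x5_benthic","slope","site1",150,"damsel_B",4.2,4
"transect_30x5_benthic","slope","site1",150,"wrasse_A",17.6,3
"transect_30x5_benthic","slope","site1",150,"wrasse_A",14.3,2
"transect_30x5_benthic","slope","site1",150,"wrasse_A",13.3,6
"clove_oil_station","slope","site1",4,"dottyback_A",1,5
"clove_oil_station","slope","site1",4,"dottyback_A",1,1
"clove_oil_station","slope","site1",4,"dottyback_A",3.1,3
"transect_50x5","slope","site1",250,"grouper_A",8.5,6
"transect_50x5","slope","site1",250,"grouper_A",11.1,1
"transect_30x5_benthic","slope","site1",150,"hawkfish_A",7.8,3
"transect_30x5_benthic","slope","site1",150,"hawkfish_A",13.9,1
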