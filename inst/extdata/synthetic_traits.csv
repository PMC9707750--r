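"species","prey_group","is_predator","predator_group"
"goby_A","cryptobenthic",FALSE,NA
"goby_B","cryptobenthic",FALSE,NA
"blenny_A","cryptobenthic",FALSE,NA
"cardinal_A","social",TRUE,"grabber"
"damsel_A","social",FALSE,NA
"damsel_B","social",FALSE,NA
"wrasse_A","epibenthic",FALSE,NA
"dottyback_A","cryptobenthic",TRUE,"grabber"
"grouper_A","epibenthic",TRUE,"engulfer"
"hawkfish_A","epibenthic",TRUE,"grabber"
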