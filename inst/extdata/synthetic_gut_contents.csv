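"study","predator_species","predator_group","size_min","size_max","prey_group","occurrences","pelagic_flag"
"study_02","pred_sp01","grabber",25.9,27.2,"social",12,FALSE
"study_05","pred_sp11","grabber",3.2,17,"social",4,FALSE
"study_10","pred_sp30","grabber",17.8,36.1,"social",8,FALSE
"study_08","pred_sp30","grabber",6.9,21.7,"social",14,FALSE
"study_12","pred_sp13","grabber",23.3,26.7,"social",10,FALSE
"study_10","pred_sp11","grabber",36.5,54,"social",9,FALSE
"study_01","pred_sp14","grabber",19.4,19.4,"social",8,FALSE
"study_05","pred_sp19","grabber",19.9,27.7,"social",10,FALSE
"study_01","pred_sp21","engulfer",19.9,38.3,"social",12,FALSE
"study_08","pred_sp10","engulfer",25.3,29.9,"cryptobenthic",9,FALSE
"study_07","pred_sp22","grabber",19.9,28.9,"social",8,FALSE
"study_03","pred_sp10","grabber",8.2,24.6,"cryptobenthic",8,FALSE
"study_07","pred_sp28","grabber",0.5,17.9,"social",12,FALSE
"study_05","pred_sp26","engulfer",13,28.7,"cryptobenthic",6,FALSE
"study_07","pred_sp10","engulfer",18.2,18.2,"social",13,FALSE
"study_05","pred_sp07","grabber",13.5,28.2,"social",9,FALSE
"study_02","pred_sp13","grabber",72.2,90.1,"cryptobenthic",5,FALSE
"study_02","pred_sp28","grabber",43.2,43.2,"social",9,FALSE
"study_09","pred_sp24","grabber",26.6,31.1,"social",4,FALSE
"study_01","pred_sp05","grabber",40.1,42,"cryptobenthic",10,FALSE
"study_06","pred_sp30","grabber",2.2,21.2,"social",11,FALSE
"study_08","pred_sp26","grabber",48.5,57.2,"epibenthic",7,FALSE
"study_07","pred_sp25","grabber",34.6,40.7,"social",8,FALSE
"study_05","pred_sp09","grabber",42,43.2,"cryptobenthic",14,FALSE
"study_12","pred_sp02","grabber",26.8,45.4,"social",9,FALSE
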