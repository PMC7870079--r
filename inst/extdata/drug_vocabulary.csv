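drug_id,canonical_name,drug_class,is_biologic,is_antitumor,default_cycle_days
fluorouracil,5-fluorouracil,fluoropyrimidine_iv,FALSE,TRUE,14
capecitabine,capecitabine,fluoropyrimidine_oral,FALSE,TRUE,21
s1,tegafur/gimeracil/oteracil (S-1),fluoropyrimidine_oral,FALSE,TRUE,21
uft,tegafur/uracil (UFT),fluoropyrimidine_oral,FALSE,TRUE,28
ftd_tpi,trifluridine/tipiracil,ftd_tpi,FALSE,TRUE,21
oxaliplatin,oxaliplatin,oxaliplatin,FALSE,TRUE,14
irinotecan,irinotecan,irinotecan,FALSE,TRUE,14
bevacizumab,bevacizumab,antiangiogenic,TRUE,TRUE,14
ramucirumab,ramucirumab,antiangiogenic,TRUE,TRUE,14
aflibercept_beta,aflibercept beta,antiangiogenic,TRUE,TRUE,14
cetuximab,cetuximab,anti_egfr,TRUE,TRUE,14
panitumumab,panitumumab,anti_egfr,TRUE,TRUE,14
pembrolizumab,pembrolizumab,other_targeted,FALSE,TRUE,21
regorafenib,regorafenib,other_targeted,FALSE,TRUE,28
leucovorin,leucovorin (folinic acid),leucovorin,FALSE,FALSE,14
gemcitabine,gemcitabine,other,FALSE,TRUE,28
sunitinib,sunitinib,other,FALSE,TRUE,28
amlodipine,amlodipine,antihypertensive,FALSE,FALSE,28
candesartan,candesartan,antihypertensive,FALSE,FALSE,28
butylscopolamine,butylscopolamine,anticholinergic,FALSE,FALSE,28
warfarin,warfarin,anticoagulant,FALSE,FALSE,28
edoxaban,edoxaban,anticoagulant,FALSE,FALSE,28
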