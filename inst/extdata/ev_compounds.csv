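"name","bcs","logp","mw","solubility","hbd","hba","psa","charge","passive","electroporation","saponin","freeze_thaw","sonication","external"
"Doxorubicin","NC(IV-only)",1.27,543.5,50,4,8,124,1,72,8,18,15,4,FALSE
"Paclitaxel","NC(no FDA oral IR)",3.97,853.9,0.3,2,11,97,0,75,2,25,12,8,FALSE
"Cisplatin","NC(IV-only)",-2.5,300,3.5,0,2,0,0,65,7,12,18,6,FALSE
"Gemcitabine","NC(IV-only)",-1.2,263.2,100,3,5,95,0,68,9,22,22,7,FALSE
"Docetaxel","NC(IV-only)",4.1,861.9,0.1,2,11,98,0,77,1.5,28,10,6,FALSE
"Methotrexate","IV",-1.85,454.4,0.3,4,9,168,-2,5,52,68,32,45,FALSE
"Riboflavin","III",-0.6,376.4,1.2,5,8,149,0,8,48,71,38,48,FALSE
"Ampicillin","III",0.87,349.4,1,3,8,115,-1,3,55,74,35,51,TRUE
"Furosemide","IV",2.03,330.7,0.5,2,5,99,-1,70,5,20,8,15,TRUE
"Warfarin","II",2.92,308.3,0.14,1,4,49,0,72,3,18,9,11,FALSE
"Digoxin","NC (conflicting II/III; NTI)",1.26,780.9,0.05,5,12,206,0,65,18,35,40,38,FALSE
"Chloroquine","I",3.81,319.9,0.7,2,4,47,1,68,8,22,14,18,FALSE
"Irinotecan","NC (primarily IV; insufficient FDA BCS)",3.27,586.7,0.2,2,9,106,0,71,5,24,11,13,FALSE
"5-Fluorouracil","III/NC (limited oral IR context)",-0.89,130.1,12.2,2,3,66,0,55,10,15,19,9,FALSE
"Caffeine","I",0.16,194.2,21.5,0,3,58,0,52,11,14,21,11,TRUE
"Quercetin","NC (not approved as drug)",1.83,302.2,0.003,5,7,131,0,69,4,19,12,14,FALSE
"Resveratrol","NC (not approved as drug)",3.05,228.2,0.3,3,3,60,0,73,6,21,13,16,FALSE
"Sildenafil","II",2.71,474.6,3.5,2,6,87,0,74,4,20,10,12,TRUE
"Curcumin","NC (not approved as drug)",3.97,368.4,0.003,2,4,93,0,76,2,26,9,7,FALSE
"Pirarubicin","NC (IV-only)",1.34,557.5,45,4,8,126,1,70,9,19,16,5,FALSE
"Tamoxifen","II",4.3,371.4,0.01,1,2,39,0,79,1,15,7,5,FALSE
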