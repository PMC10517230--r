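biomarker,condition_label,group,sex,age_min,age_max,age_unit,direction,threshold,threshold_unit,use_adjusted,source
ferritin,iron_deficiency,PSC,any,6,59,months,below,12,ug/L,TRUE,WHO 2020 serum ferritin thresholds; inflammation-adjusted
ferritin,iron_deficiency,WRA,any,15,49,years,below,15,ug/L,TRUE,WHO 2020 serum ferritin thresholds; inflammation-adjusted
stfr,iron_deficiency_stfr,PSC,any,6,59,months,above,8.3,mg/L,TRUE,BRINDA-project convention; assay-dependent - review before use
stfr,iron_deficiency_stfr,WRA,any,15,49,years,above,8.3,mg/L,TRUE,BRINDA-project convention; assay-dependent - review before use
retinol,vitamin_a_deficiency,PSC,any,6,59,months,below,0.7,umol/L,TRUE,WHO 2011 serum retinol; inflammation-adjusted for PSC
retinol,vitamin_a_deficiency,WRA,any,15,49,years,below,0.7,umol/L,FALSE,WHO 2011 serum retinol; unadjusted for WRA
rbp,vitamin_a_deficiency_rbp,PSC,any,6,59,months,below,0.7,umol/L,TRUE,Retinol-equivalent RBP threshold; survey-specific calibration recommended
zinc,zinc_deficiency,PSC,any,6,59,months,below,9.9,umol/L,TRUE,IZiNCG morning nonfasting <65 ug/dL; fasting status not modelled
zinc,zinc_deficiency,WRA,any,15,49,years,below,10.1,umol/L,TRUE,IZiNCG morning nonfasting <66 ug/dL; fasting status not modelled
folate_serum,folate_deficiency,WRA,any,15,49,years,below,10,nmol/L,FALSE,WHO serum folate possible deficiency <10 nmol/L
b12,b12_deficiency,WRA,any,15,49,years,below,150,pmol/L,FALSE,WHO serum B-12 deficiency <150 pmol/L
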