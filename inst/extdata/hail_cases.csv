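factor,level,count,exhaustive
age,40–49 years,51,TRUE
age,50–59 years,69,TRUE
age,60–69 years,55,TRUE
age,70–79 years,17,TRUE
age,≥80 years,8,TRUE
gender,Male,105,TRUE
gender,Female,95,TRUE
education,Illiterate,5,TRUE
education,Literate,195,TRUE
symptom,Blurry vision,20,FALSE
symptom,Decreased vision,51,FALSE
symptom,Headache/Pain,15,FALSE
diagnostic_context,Developed during follow-up,54,FALSE
diagnostic_context,Diagnosed in routine checkup,10,FALSE
diagnostic_context,Other/NA,40,FALSE
glaucoma_type,Primary,198,TRUE
glaucoma_type,Secondary,2,TRUE
duration,Newly diagnosed,144,TRUE
duration,≤1 year,4,TRUE
duration,2–5 year,12,TRUE
duration,6–9 year,29,TRUE
duration,≥10 year,11,TRUE
comorbidity,Diabetes Mellitus,93,FALSE
comorbidity,Hypertension,41,FALSE
comorbidity,Asthma,4,FALSE
comorbidity,Cardiovascular Disease,2,FALSE
comorbidity,Cataract,22,FALSE
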