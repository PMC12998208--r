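column,type,units,description
id,integer,,participant identifier
cycle,integer,,survey cycle (2 / 5 / 6)
age,numeric,years,age at examination (20-79)
sex,character,,male / female
ethnicity,character,,white / other
asian,logical,,Asian ethnicity flag (lower waist-circumference thresholds)
education,character,,elementary / secondary / postsecondary
marital,character,,married / widowed_sep_div / single
smoking,character,,never / ever
country_of_birth,character,,canada / foreign
parity,character,,females only: 0 / 1 / 2 / 3plus (NA for males)
fish,numeric,times/month,fish and shellfish consumption
mvpa,numeric,min/day,moderate-to-vigorous physical activity
pregnant,logical,,currently pregnant (excluded from analysis)
t1d,logical,,type 1 diabetes (excluded from analysis)
pfoa,numeric,ug/L,plasma PFOA concentration (NA when below LOD before imputation)
pfos,numeric,ug/L,plasma PFOS concentration
pfhxs,numeric,ug/L,plasma PFHxS concentration
pfda,numeric,ug/L,plasma PFDA concentration
pfna,numeric,ug/L,plasma PFNA concentration
nd_pfoa,logical,,PFOA below limit of detection
nd_pfos,logical,,PFOS below limit of detection
nd_pfhxs,logical,,PFHxS below limit of detection
nd_pfda,logical,,PFDA below limit of detection
nd_pfna,logical,,PFNA below limit of detection
wc,numeric,cm,waist circumference
tg,numeric,mmol/L,fasting serum triglycerides
hdl,numeric,mmol/L,serum HDL cholesterol
glu,numeric,mmol/L,non-fasting serum glucose (auxiliary outcome)
sbp,numeric,mmHg,average resting systolic blood pressure
dbp,numeric,mmHg,average resting diastolic blood pressure
hba1c,numeric,%,whole-blood glycated hemoglobin A1c
med_lipid,logical,,taking lipid-lowering medication
med_bp,logical,,taking antihypertensive medication
med_diabetes,logical,,taking diabetes medication
dx_htn,logical,,prior hypertension diagnosis
dx_t2d,logical,,prior type 2 diabetes diagnosis
site,integer,,collection-site cluster id
weight,numeric,,main survey analysis weight
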