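# Default morbidity lexicon: condition-id -> surface keywords/phrases used for
# rule-based extraction from free-text condition fields.
#
# Only the mental_disorders keyword list is a published, verbatim clinical
# keyword set; every other entry is a reconstructed set of plausible surface
# forms and is intended to be reviewed and edited for any new data source.
# Schema per entry:
#   display_name:    human-readable condition name
#   keywords:        list of lowercase tokens / multi-token phrases
#   exclusions:      optional phrases whose match suppresses this condition
#                    for the overlapping span
#   fuzzy_threshold: optional per-condition override of the default similarity
#                    threshold (0-100)
vitamin_deficiency:
  display_name: "Vitamin deficiency"
  keywords: [vitamin deficiency, vitamin d deficiency, vit d deficiency, low vitamin d, hypovitaminosis, b12 deficiency, folate deficiency]
mental_disorders:
  display_name: "Common mental disorders"
  keywords: [anxiety, depression, panic, psychological, stress, bpad, bipolar, personality, borderline, schizophrenia, intellectually, bpd, fatigue, ptsd, psychosis, bulimia, psych, substance, suicidal, schizoaffective]
blood_disorders:
  display_name: "Anemia and other blood disorders"
  keywords: [anaemia, anemia, thalassaemia, thalassemia, thrombocytopenia, haemoglobinopathy, polycythaemia, anemic]
asthma:
  display_name: "Asthma"
  keywords: [asthma, asthmatic]
thyroid_disease:
  display_name: "Thyroid disease"
  keywords: [thyroid, hypothyroidism, hyperthyroidism, hypothyroid, hyperthyroid, hashimoto, graves disease, goitre]
endometrial_disease:
  display_name: "Endometrial disease"
  keywords: [endometriosis, endometrial, adenomyosis, fibroid, fibroids]
cardiovascular_disease:
  display_name: "Cardiovascular disease"
  keywords: [cardiac, cardiovascular, arrhythmia, palpitations, cardiomyopathy, murmur, svt]
pcos:
  display_name: "Polycystic ovary syndrome"
  keywords: [pcos, polycystic, pco]
iron_deficiency_anemia:
  display_name: "Iron deficiency anemia"
  keywords: [iron deficiency anaemia, iron deficiency anemia, iron deficiency, low iron, low ferritin]
migraine:
  display_name: "Migraine"
  keywords: [migraine, migraines]
urinary_tract_infection:
  display_name: "Urinary tract infections"
  keywords: [uti, urinary tract infection, cystitis, pyelonephritis, recurrent uti]
diabetes_mellitus:
  display_name: "Diabetes mellitus (preexisting)"
  keywords: [diabetes, t1dm, t2dm, iddm, niddm, diabetic]
  exclusions: [gestational diabetes, gdm]
musculoskeletal_disease:
  display_name: "Musculoskeletal disease"
  keywords: [scoliosis, arthritis, back pain, sciatica, osteoporosis, fibromyalgia]
hypertension:
  display_name: "Hypertension (preexisting)"
  keywords: [hypertension, hypertensive, htn]
  exclusions: [pregnancy induced hypertension, gestational hypertension, pih]
kidney_disease:
  display_name: "Kidney disease"
  keywords: [kidney disease, nephropathy, kidney stones, nephrectomy, renal]
substance_use:
  display_name: "Substance use"
  keywords: [substance use, substance abuse, smoker, smoking, alcohol, cannabis, methadone, heroin, methamphetamine, drug use]
respiratory_disease:
  display_name: "Other respiratory disease"
  keywords: [bronchiectasis, sleep apnoea, sleep apnea, copd, tuberculosis, pneumonia, osa]
bowel_disease:
  display_name: "Bowel disease"
  keywords: [crohns, colitis, coeliac, celiac, ibs, bowel disease]
genital_herpes:
  display_name: "Genital herpes"
  keywords: [herpes, hsv, genital herpes]
hemorrhoids:
  display_name: "Hemorrhoids"
  keywords: [haemorrhoids, hemorrhoids, piles]
autoimmune_disease:
  display_name: "Autoimmune disease"
  keywords: [lupus, sle, sjogren, autoimmune, rheumatoid]
infertility:
  display_name: "Infertility"
  keywords: [infertility, subfertility, infertile, ivf]
epilepsy:
  display_name: "Epilepsy"
  keywords: [epilepsy, epileptic, seizures]
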