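# Default complications lexicon (same schema as the morbidity lexicon); used
# to extract obstetric/labour/fetal outcome flags from the complications
# free-text column when explicit 0/1 outcome columns are absent. Reconstructed
# surface forms; review before use on any new data source.
gdm:
  display_name: "Gestational diabetes mellitus"
  keywords: [gdm, gestational diabetes, gestational diabetes mellitus, gdm diet controlled, gdm insulin]
preeclampsia:
  display_name: "Preeclampsia"
  keywords: [preeclampsia, pre eclampsia, pet]
pih:
  display_name: "Pregnancy-induced hypertension"
  keywords: [pih, pregnancy induced hypertension, gestational hypertension]
preterm:
  display_name: "Preterm birth"
  keywords: [preterm, preterm birth, premature labour, premature delivery]
induction:
  display_name: "Induction of labour"
  keywords: [induction, induced, iol, induction of labour]
cesarean:
  display_name: "Cesarean delivery"
  keywords: [cesarean, caesarean, lscs, emcs, elcs, c section]
birth_defect:
  display_name: "Birth defect"
  keywords: [birth defect, congenital anomaly, congenital, cleft]
scn_nicu:
  display_name: "Special care nursery / NICU admission"
  keywords: [scn, nicu, special care nursery, neonatal intensive care]
shoulder_dystocia:
  display_name: "Shoulder dystocia"
  keywords: [shoulder dystocia]
macrosomia:
  display_name: "Macrosomia"
  keywords: [macrosomia, macrosomic, lga]
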