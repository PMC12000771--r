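condition,a,b,c,d
overweight,27542,7042,10617,3301
obesity,30570,6907,7589,3436
substance_use,33079,9390,5080,953
thyroid_disease,35502,9424,2657,919
hypertension,37792,10129,367,214
vitamin_deficiency,27527,6956,10632,3387
infertility,38077,10300,82,43
advanced_age,30476,7113,7683,3230
multimorbidity,23612,5356,14547,4987
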