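disease,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18
"Diabetes",0.34,0.40,0.19,0.07,,,,,,,,,,,,,,
"Arthritis",0.42,0.12,0.09,0.32,0.06,,,,,,,,,,,,,
"Coronary heart disease",0.22,0.30,0.26,0.21,0.01,,,,,,,,,,,,,
"Hearing impairments",0.02,0.18,0.44,0.34,0.01,,,,,,,,,,,,,
"Cataracts",,0.01,0.01,0.06,0.82,0.10,0.00,,,,,,,,,,,
"COPD",,,,,0.10,0.85,0.04,0.01,,,,,,,,,,
"Stroke",,,,,,0.03,0.75,0.20,0.02,,,,,,,,,
"Osteoporosis",,,,,,0.01,0.10,0.34,0.32,0.14,0.06,0.03,,,,,,
"Rheumatoid arthritis",,,,,,0.01,0.10,0.34,0.33,0.13,0.06,0.02,,,,,,
"Heart failure",,,,,,,,0.08,0.21,0.35,0.24,0.12,,,,,,
"Epilepsy",,,,,,,,0.03,0.12,0.33,0.38,0.14,,,,,,
"Glaucoma",,,,,,,,,,0.05,0.26,0.68,0.01,,,,,
"Dementia",,,,,,,,,,,,0.01,0.41,0.29,0.22,0.05,0.01,
"Inflammatory bowel",,,,,,,,,,,,,0.39,0.40,0.20,0.01,,
"Macular degeneration",,,,,,,,,,,,,0.18,0.30,0.43,0.08,0.01,
"Schizophrenia",,,,,,,,,,,,,,0.01,0.15,0.83,0.01,
"Parkinson",,,,,,,,,,,,,,,,0.02,0.92,0.06
"Multiple sclerosis",,,,,,,,,,,,,,,,,0.06,0.94
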