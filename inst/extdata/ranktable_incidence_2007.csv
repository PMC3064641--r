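disease,1,2,3,4,5,6,7,8,9,10,11,12,13,14,15,16,17,18
"Coronary heart disease",0.30,0.34,0.22,0.11,0.03,,,,,,,,,,,,,
"Cataracts",0.22,0.43,0.28,0.07,0.01,,,,,,,,,,,,,
"Diabetes",0.04,0.11,0.33,0.37,0.14,0.01,,,,,,,,,,,,
"Arthritis",0.38,0.04,0.05,0.08,0.11,0.08,0.05,0.08,0.06,0.03,0.02,0.01,,,,,,
"Hearing impairments",0.05,0.07,0.11,0.28,0.34,0.12,0.02,0.01,,,,,,,,,,
"COPD",,0.01,0.02,0.09,0.27,0.38,0.14,0.08,0.02,,,,,,,,,
"Heart failure",,,,,0.05,0.25,0.44,0.21,0.03,,,,,,,,,
"Stroke",,,,,0.02,0.11,0.28,0.45,0.13,0.01,,,,,,,,
"Osteoporosis",,,,0.01,0.02,0.04,0.05,0.10,0.35,0.21,0.13,0.07,0.02,0.01,,,,
"Dementia",,,,,,0.01,0.01,0.05,0.28,0.33,0.20,0.09,0.02,0.00,,,,
"Rheumatoid arthritis",,,,,,,,,0.08,0.30,0.44,0.16,0.02,0.00,,,,
"Macular degeneration",,,,,,,,0.01,0.06,0.10,0.12,0.22,0.17,0.08,0.16,0.06,0.01,
"Glaucoma",,,,,,,,,,0.02,0.09,0.40,0.37,0.08,0.04,0.00,,
"Epilepsy",,,,,,,,,,,,0.05,0.30,0.49,0.15,0.01,,
"Inflammatory bowel diseases",,,,,,,,,,,,0.01,0.08,0.31,0.57,0.03,,
"Parkinson",,,,,,,,,,,,,,,0.05,0.79,0.15,
"Schizophrenia",,,,,,,,,,,,0.01,0.01,0.01,0.03,0.11,0.50,0.33
"Multiple sclerosis",,,,,,,,,,,,,,,,,0.33,0.67
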