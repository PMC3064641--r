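sex,age_class,population
F,0-4,481665
F,5-9,486555
F,10-14,486555
F,15-19,481665
F,20-24,482625
F,25-29,495000
F,30-34,537500
F,35-39,632460
F,40-44,639930
F,45-49,598885
F,50-54,556640
F,55-59,532500
F,60-64,474300
F,65-69,375375
F,70-74,330000
F,75-79,292500
F,80-84,234950
F,85+,227200
M,0-4,503335
M,5-9,508445
M,10-14,508445
M,15-19,503335
M,20-24,492375
M,25-29,495000
M,30-34,537500
M,35-39,637540
M,40-44,645070
M,45-49,606115
M,50-54,563360
M,55-59,532500
M,60-64,455700
M,65-69,339625
M,70-74,270000
M,75-79,207500
M,80-84,135050
M,85+,92800
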