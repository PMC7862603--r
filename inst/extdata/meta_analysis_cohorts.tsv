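accession	n_patients
GSE14333	290
GSE17536	177
GSE29623	65
GSE33113	90
GSE37892	130
GSE38832	122
GSE72970	124
GSE87211	203
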