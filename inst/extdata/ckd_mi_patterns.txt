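# Related-disease name patterns for chronic kidney disease and myocardial
# infarction latent-feature screening. One lowercase substring per line;
# a trailing ** matches any characters.
heart
cardi**
athero**
arterio**
coronary
kidney
renal
nephro**
glomer**
diabe**
vascul**
capil**
hypertens**
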