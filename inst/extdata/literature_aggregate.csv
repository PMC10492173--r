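test,n,mean,sd,unit,verdict
age,2843,26,26.6,years,equivalent
total_t,2378,72.9,84,ng/dL,equivalent
dheas,1288,265.5,293.7,ug/dL,literature-lower
bmi,2843,27.4,28.3,kg/m2,equivalent
free_t,911,11.4,13.7,pg/mL,literature-higher
fpg,2080,89.7,90.6,mg/dL,equivalent
fsh,1883,5.9,6.4,U/L,equivalent
lh,1883,8.2,10.1,U/L,literature-lower
tsh,767,2.2,2.6,mU/L,equivalent
prl,167,21.4,26.2,ng/mL,equivalent
fi,2080,14.2,18.6,mU/L,equivalent
shbg,1423,44.5,53.8,nmol/L,literature-lower
amh,482,9.9,12.3,ng/mL,equivalent
homa_ir,1135,3,3.9,,equivalent
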