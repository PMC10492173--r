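test,n,pct_sets,mean,sd,median,min,max,pct_uncertain,pct_outliers
age,661,41.7,25.5,5.3,24,13,44,0,0
total_t,552,34.8,55.9,37.9,50,1.5,375.1,2.2,0.5
dheas,381,24,396.5,165.2,400,15,1046,0.8,1
bmi,240,15.1,24.4,6.4,22.4,15.4,48.6,0,0
lh_fsh,236,14.9,2.2,1.4,1.9,0.1,7.9,0.4,0.4
free_t,226,14.3,5.9,4.4,4.9,0.1,30,6.6,1.3
fpg,219,13.8,94.2,17.6,93,50,157,0.9,0.9
fsh,214,13.5,5.8,3.1,5.5,0.6,26.9,0.5,0.5
hba1c,211,13.3,5.5,0.8,5.3,4.1,9.3,0.5,1.9
lh,206,13,12.9,13.6,8.9,0.3,85,0.5,1.4
tsh,176,11.1,2.4,1.6,2,0.1,8.9,0.6,0.6
prl,140,8.8,24.2,23.9,16.3,0.8,173,1.4,0.7
e2,138,8.7,79.3,88.2,46.9,3.5,516,6.4,1.4
fi,131,8.3,12.9,12,9,1.2,72,8.2,2.2
p,89,5.6,5,10.1,0.6,0.03,47,12.2,1.1
shbg,72,4.5,84.4,70.7,65.5,14,339.9,0,0
amh,61,3.8,10.2,6,9.2,0.02,26,3.2,1.6
homa_ir,57,3.6,2.1,2.4,1.6,0.3,17.7,3.4,1.7
ft4,48,3,1.1,0.2,1.1,0.8,1.7,4.1,2
ohp17,44,2.8,125.7,111.8,79.8,10,459,4.5,0
vitd,41,2.6,26.4,17.3,24,4,80,0,0
fer,31,2,37.8,33,28.5,6,167,0,0
tc,30,1.9,219.8,55.2,225.5,105,317,0,0
ldl,27,1.7,132.1,46.6,128,67,290,0,0
tg,25,1.6,129.9,75.7,125,46,300,0,0
a4,23,1.5,349.9,376.3,209.1,1.7,1440,17.4,0
alt,23,1.5,90,106.4,37,12,412,0,0
hdl,23,1.5,60.7,18.8,53,31,94,0,0
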