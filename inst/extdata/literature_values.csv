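study,test,mean,sd,unit,code
diamanti,age,24.3,5.6,years,a
cai,age,27.7,5.2,years,a
tosi,age,23.1,5.3,years,b
paschou,age,25.5,6.1,years,a
sova,age,28.1,4.3,years,c
kumar,age,27.5,6.6,years,a
bahceci,age,22.4,3.5,years,b
homburg,age,31.6,4.4,years,c
pigny,age,29,4.4,years,c
wright,age,24.8,6.2,years,a
diamanti,total_t,79,28.9,ng/dL,c
cai,total_t,64.9,26.8,ng/dL,a
paschou,total_t,85.8,36.5,ng/dL,c
sova,total_t,46.2,20.2,ng/dL,a
kumar,total_t,99.7,89.2,ng/dL,c
bahceci,total_t,99,35,ng/dL,c
pigny,total_t,45,21.6,ng/dL,b
wright,total_t,50,25.3,ng/dL,a
diamanti,dheas,286.3,119.8,ug/dL,b
paschou,dheas,288.3,127.4,ug/dL,b
kumar,dheas,163.9,83.4,ug/dL,b
wright,dheas,265.3,118.3,ug/dL,b
diamanti,bmi,26.7,7.4,kg/m2,a
cai,bmi,26.4,5.7,kg/m2,a
tosi,bmi,27.6,7.1,kg/m2,c
paschou,bmi,27.8,7,kg/m2,c
sova,bmi,27.3,6.3,kg/m2,c
kumar,bmi,36,9.2,kg/m2,c
bahceci,bmi,23.5,5.9,kg/m2,a
homburg,bmi,24.9,2.4,kg/m2,a
pigny,bmi,26,6.1,kg/m2,a
wright,bmi,21.9,2.1,kg/m2,b
cai,free_t,13.7,7.3,pg/mL,c
kumar,free_t,9.2,5.8,pg/mL,c
bahceci,free_t,1.9,1.1,pg/mL,b
diamanti,fpg,96.8,13.7,mg/dL,a
tosi,fpg,85.1,10,mg/dL,b
paschou,fpg,83.1,7.8,mg/dL,b
sova,fpg,91.8,9,mg/dL,a
kumar,fpg,88,12.3,mg/dL,b
bahceci,fpg,90.5,9.2,mg/dL,a
wright,fpg,80.8,8.6,mg/dL,b
diamanti,fsh,5.5,1.7,U/L,a
cai,fsh,6.23,2.5,U/L,a
sova,fsh,6.2,2.1,U/L,a
bahceci,fsh,6.9,5.6,U/L,a
homburg,fsh,5.1,1.4,U/L,a
pigny,fsh,5.5,1.6,U/L,a
wright,fsh,5.8,3.2,U/L,a
diamanti,lh,7.9,5.7,U/L,b
cai,lh,8.8,6.4,U/L,b
sova,lh,6.9,4.8,U/L,b
bahceci,lh,7.6,5,U/L,b
homburg,lh,8.8,5.2,U/L,b
pigny,lh,6.7,4,U/L,b
wright,lh,16.6,9.7,U/L,a
cai,tsh,2.3,1.2,mU/L,a
bahceci,tsh,1.7,1.18,mU/L,b
wright,tsh,2.5,1,mU/L,a
bahceci,prl,24.7,17.1,ng/mL,a
wright,prl,16.6,9.7,ng/mL,b
diamanti,fi,13.3,14.4,mU/L,a
tosi,fi,15.7,11.8,mU/L,a
paschou,fi,15.2,4.8,mU/L,a
sova,fi,11.2,11.5,mU/L,a
kumar,fi,19.7,14.7,mU/L,c
bahceci,fi,10.2,6.2,mU/L,a
wright,fi,11.3,6.9,mU/L,a
diamanti,shbg,38,20.6,nmol/L,b
paschou,shbg,31.5,12.5,nmol/L,b
sova,shbg,50.9,27.7,nmol/L,b
bahceci,shbg,115,38,nmol/L,c
sova,amh,9.3,6.6,ng/mL,a
homburg,amh,10.9,8.5,ng/mL,a
pigny,amh,11.4,8,ng/mL,a
tosi,homa_ir,3.4,2.8,,c
paschou,homa_ir,3.1,1.9,,c
sova,homa_ir,2.6,2.8,,a
wright,homa_ir,2.3,1.5,,a
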