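# scratch: write inst/extdata fixtures (test catalog + literature/subreddit tables)
suppressMessages(library(jsonlite))

# test id, full name, canonical unit, distribution family, render digits, class
# class: androgen-like tests get x3 upper widening, others x2 (lower /2)
defs <- list(
 age     = list(name="Age", unit="years", syn=c("age"), alt=list(),
                healthy=c(18,45), plaus=c(13,70), class="demographic", family="normal", digits=0),
 bmi     = list(name="BMI", unit="kg/m2", syn=c("bmi"), alt=list(),
                healthy=c(18.5,25), plaus=c(13,55), class="demographic", family="normal", digits=1),
 total_t = list(name="Total testosterone", unit="ng/dL", syn=c("total testosterone","total t","testosterone"),
                alt=list("nmol/L"=28.84, "ng/mL"=100), healthy=c(20,75), class="androgen", family="normal", digits=0),
 dheas   = list(name="DHEA sulfate", unit="ug/dL", syn=c("dhea-s","dheas","dhea s","dhea sulfate","dehydroepiandrosterone sulfate"),
                alt=list("umol/L"=36.85), healthy=c(59,328), class="androgen", family="normal", digits=0),
 lh_fsh  = list(name="LH to FSH ratio", unit="", syn=c("lh/fsh","lh:fsh","lh to fsh ratio"),
                alt=list(), healthy=c(0.3,2.5), class="androgen", family="normal", digits=1),
 free_t  = list(name="Free testosterone", unit="pg/mL", syn=c("free testosterone","free t"),
                alt=list("pmol/L"=0.2884, "ng/dL"=10), healthy=c(0.5,9), class="androgen", family="normal", digits=1),
 fpg     = list(name="Fasting plasma glucose", unit="mg/dL", syn=c("fasting glucose","fasting plasma glucose","fpg","fasting blood glucose"),
                alt=list("mmol/L"=18.016), healthy=c(70,100), class="general", family="normal", digits=0),
 fsh     = list(name="Follicle stimulating hormone", unit="U/L", syn=c("fsh","follicle stimulating hormone"),
                alt=list("mIU/mL"=1), healthy=c(1.5,12), class="general", family="normal", digits=1),
 hba1c   = list(name="Hemoglobin A1c", unit="%", syn=c("hba1c","a1c","hb a1c","glycated hemoglobin"),
                alt=list(), healthy=c(4,5.6), class="general", family="normal", digits=1),
 lh      = list(name="Luteinizing hormone", unit="U/L", syn=c("lh","luteinizing hormone"),
                alt=list("mIU/mL"=1), healthy=c(1.5,76), class="androgen", family="lognormal", digits=1),
 tsh     = list(name="Thyroid stimulating hormone", unit="mU/L", syn=c("tsh","thyroid stimulating hormone"),
                alt=list("uIU/mL"=1), healthy=c(0.4,4.5), plaus=c(0.05,10), class="general", family="normal", digits=1),
 prl     = list(name="Prolactin", unit="ng/mL", syn=c("prolactin","prl"),
                alt=list("mIU/L"=0.04717, "ug/L"=1), healthy=c(4,25), plaus=c(2,200), class="general", family="lognormal", digits=1),
 e2      = list(name="Estradiol", unit="pg/mL", syn=c("estradiol","oestradiol","e2"),
                alt=list("pmol/L"=0.27241), healthy=c(15,350), plaus=c(5,700), class="general", family="normal", digits=0),
 fi      = list(name="Fasting insulin", unit="mU/L", syn=c("fasting insulin","insulin"),
                alt=list("pmol/L"=0.16667, "uIU/mL"=1), healthy=c(2,20), class="androgen", family="lognormal", digits=1),
 p       = list(name="Progesterone", unit="ng/mL", syn=c("progesterone"),
                alt=list("nmol/L"=0.31447), healthy=c(0.1,25), plaus=c(0.05,60), class="general", family="lognormal", digits=2),
 shbg    = list(name="Sex hormone binding globulin", unit="nmol/L", syn=c("shbg","sex hormone binding globulin"),
                alt=list(), healthy=c(18,144), class="general", family="lognormal", digits=1),
 amh     = list(name="Anti-Mullerian hormone", unit="ng/mL", syn=c("amh","anti-mullerian hormone","antimullerian hormone"),
                alt=list("pmol/L"=0.14), healthy=c(1,10), class="androgen", family="lognormal", digits=1),
 homa_ir = list(name="HOMA-IR", unit="", syn=c("homa-ir","homa ir","homa"),
                alt=list(), healthy=c(0.5,2.5), class="androgen", family="lognormal", digits=2),
 ft4     = list(name="Free thyroxine", unit="ng/dL", syn=c("free t4","ft4","free thyroxine"),
                alt=list("pmol/L"=0.0777), healthy=c(0.8,1.8), class="general", family="normal", digits=2),
 ohp17   = list(name="17-hydroxyprogesterone", unit="ng/dL", syn=c("17-ohp","17 ohp","17-hydroxyprogesterone"),
                alt=list("nmol/L"=33.1), healthy=c(20,200), class="androgen", family="normal", digits=0),
 vitd    = list(name="Vitamin D", unit="ng/mL", syn=c("vitamin d","vit d","25-oh vitamin d"),
                alt=list("nmol/L"=0.4006), healthy=c(20,50), class="general", family="normal", digits=0),
 fer     = list(name="Ferritin", unit="ng/mL", syn=c("ferritin"),
                alt=list("ug/L"=1), healthy=c(12,150), class="general", family="normal", digits=0),
 tc      = list(name="Total cholesterol", unit="mg/dL", syn=c("total cholesterol","cholesterol"),
                alt=list("mmol/L"=38.67), healthy=c(125,200), class="general", family="normal", digits=0),
 ldl     = list(name="LDL cholesterol", unit="mg/dL", syn=c("ldl"),
                alt=list("mmol/L"=38.67), healthy=c(50,130), class="general", family="normal", digits=0),
 tg      = list(name="Triglycerides", unit="mg/dL", syn=c("triglycerides","tg"),
                alt=list("mmol/L"=88.57), healthy=c(40,150), class="general", family="normal", digits=0),
 a4      = list(name="Androstenedione", unit="ng/dL", syn=c("androstenedione","a4"),
                alt=list("nmol/L"=28.64, "ng/mL"=100), healthy=c(30,200), class="androgen", family="normal", digits=0),
 alt     = list(name="Alanine transaminase", unit="U/L", syn=c("alt","alanine transaminase"),
                alt=list(), healthy=c(7,56), plaus=c(3.5,500), class="general", family="normal", digits=0),
 hdl     = list(name="HDL cholesterol", unit="mg/dL", syn=c("hdl"),
                alt=list("mmol/L"=38.67), healthy=c(40,90), class="general", family="normal", digits=0)
)

tests <- lapply(defs, function(d) {
  if (is.null(d$plaus)) {
    mult <- if (d$class == "androgen") 3 else 2
    d$plaus <- c(d$healthy[1] / 2, d$healthy[2] * mult)
  }
  list(name = d$name, synonyms = d$syn, unit = d$unit, alt_units = d$alt,
       healthy = d$healthy, plausible = d$plaus, class = d$class,
       family = d$family, digits = d$digits)
})
write_json(list(version = 1L, tests = tests),
           "inst/extdata/test_catalog.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)

# subreddit cohort summary (n, % of sets, mean, SD, median, min, max, % uncertain, % outliers removed)
sub <- read.csv(text = "test,n,pct_sets,mean,sd,median,min,max,pct_uncertain,pct_outliers
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
alt,23,1.5,90.0,106.4,37,12,412,0,0
hdl,23,1.5,60.7,18.8,53,31,94,0,0", stringsAsFactors = FALSE)
write.csv(sub, "inst/extdata/subreddit_summary.csv", row.names = FALSE, quote = FALSE)

# literature cohorts (study context)
coh <- read.csv(text = 'study,n,cycle_phase,fasting
diamanti,634,Follicular,Fasting
cai,600,Early Follicular,Fasting
tosi,375,Not Specified,Fasting
paschou,372,Early Follicular,Fasting
sova,319,Early Follicular,Fasting
kumar,213,Follicular,Fasting
bahceci,98,Follicular,Fasting
homburg,90,Early Follicular,Not Specified
pigny,73,Early Follicular,Not Specified
wright,69,Early Follicular,Fasting', stringsAsFactors = FALSE)
write.csv(coh, "inst/extdata/literature_cohorts.csv", row.names = FALSE, quote = FALSE)

# per-study per-test mean/SD with printed comparison code
# code: a = equivalent, b = literature lower, c = literature higher
vals <- 'study,test,mean,sd,unit,code
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
wright,homa_ir,2.3,1.5,,a'
write.csv(read.csv(text = vals, stringsAsFactors = FALSE),
          "inst/extdata/literature_values.csv", row.names = FALSE, quote = FALSE)

# aggregate literature table (printed aggregate n / mean / SD and verdicts)
agg <- 'test,n,mean,sd,unit,verdict
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
homa_ir,1135,3,3.9,,equivalent'
write.csv(read.csv(text = agg, stringsAsFactors = FALSE),
          "inst/extdata/literature_aggregate.csv", row.names = FALSE, quote = FALSE)
cat("fixtures written\n")
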