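study,n,cycle_phase,fasting
diamanti,634,Follicular,Fasting
cai,600,Early Follicular,Fasting
tosi,375,Not Specified,Fasting
paschou,372,Early Follicular,Fasting
sova,319,Early Follicular,Fasting
kumar,213,Follicular,Fasting
bahceci,98,Follicular,Fasting
homburg,90,Early Follicular,Not Specified
pigny,73,Early Follicular,Not Specified
wright,69,Early Follicular,Fasting
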