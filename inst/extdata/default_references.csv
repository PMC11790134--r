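metal,background,screening,standard_limit,toxic_response,mdl,sigma
Pb,50,120,120,5,0.25,0.1
Cr,100,200,200,2,0.16,0.1
Mn,2000,4000,4000,1,0.15,0.1
Cu,100,200,200,5,0.05,0.1
Zn,300,600,600,1,0.21,0.1
Co,50,100,100,5,0.12,0.1
Ni,100,200,200,5,0.54,0.1
As,20,30,30,10,3e-04,0.1
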