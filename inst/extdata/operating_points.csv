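# hemopso operating-point fixtures: 12 experimental hemolysis measurements
# (3 FDA-nozzle, 5 FDA-pump, 4 capillary-tube flows). mih_exp/mih_unc are the
# central MIH and symmetric uncertainty; flow rates in l/min as printed.
# Fluid columns: viscosity mu [mPa s], density rho [kg/m^3] (NA where not
# reported), rotor speed n_rpm (pumps only), Reynolds number at the narrowest
# point, hematocrit fraction and total hemoglobin Hb [mg/dl].
label,group,flow_lmin,mih_exp,mih_unc,mu_mpas,rho_kgm3,n_rpm,re,hct,hb_mgdl
5LSC,nozzle,5.05,0.29,0.25,4.21,1040,NA,6650,0.36,NA
6LGC,nozzle,5.94,0.02,0.13,4.21,1040,NA,7860,0.36,NA
6LSC,nozzle,6.07,1.24,0.67,4.21,1040,NA,8020,0.36,NA
OP1,pump,2.5,0.80,1.28,3.4,1030,2500,209338,NA,12000
OP3,pump,4.5,1.24,0.97,3.4,1030,3500,293073,NA,12000
OP4,pump,6.0,0.78,0.59,3.4,1030,2500,209338,NA,12000
OP5,pump,6.0,0.77,0.47,3.4,1030,3500,293073,NA,12000
OP6,pump,7.0,2.44,1.89,3.4,1030,3500,293073,NA,12000
ct2230,ct,0.21,8.7,5.9,2.0,NA,NA,2230,0.24,8000
ct3500,ct,0.33,9.4,4.9,2.0,NA,NA,3500,0.24,8000
ct4500,ct,0.42,37.9,10.0,2.0,NA,NA,4500,0.24,8000
ct5100,ct,0.48,85.5,19.5,2.0,NA,NA,5100,0.24,8000
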