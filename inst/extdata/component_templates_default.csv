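# Default component parameter table, v1.
# Group-mean peak amplitudes (uV, by electrode) and peak latencies (ms, at Cz) with
# between-subject SDs for the MMN, e-P3a, l-P3a and RON components in the
# novel-minus-standard (NS) and deviant-minus-standard (DS) difference waveforms,
# for three age groups. These values define the conditions the synthetic-data
# generator emulates. flag=sign_corrected marks one cell whose published positive
# value contradicts the component's polarity and is stored negated (see vignette).
component,group,contrast,electrode,amplitude,amplitude_sd,latency,latency_sd,flag
MMN,Young,NS,Cz,-2.8,4.6,163,31,
MMN,Young,DS,Cz,-3.0,2.4,220,24,
MMN,MiddleAged,NS,Cz,-5.0,3.9,197,31,
MMN,MiddleAged,DS,Cz,-2.9,2.0,230,40,
MMN,Old,NS,Cz,-2.3,3.4,221,35,
MMN,Old,DS,Cz,-1.4,1.6,202,50,
eP3a,Young,NS,Fz,14.8,6.9,297,26,
eP3a,Young,NS,Cz,19.3,8.9,297,26,
eP3a,Young,NS,Pz,13.2,5.6,297,26,
eP3a,Young,DS,Fz,4.3,3.7,325,30,
eP3a,Young,DS,Cz,5.9,4.5,325,30,
eP3a,Young,DS,Pz,5.3,3.2,325,30,
eP3a,MiddleAged,NS,Fz,9.8,3.8,380,21,
eP3a,MiddleAged,NS,Cz,12.9,4.3,380,21,
eP3a,MiddleAged,NS,Pz,9.6,4.5,380,21,
eP3a,MiddleAged,DS,Fz,3.0,1.9,376,19,
eP3a,MiddleAged,DS,Cz,4.3,2.8,376,19,
eP3a,MiddleAged,DS,Pz,3.4,3.4,376,19,
eP3a,Old,NS,Fz,9.6,4.2,384,19,
eP3a,Old,NS,Cz,12.8,5.2,384,19,
eP3a,Old,NS,Pz,9.1,5.4,384,19,
eP3a,Old,DS,Fz,2.7,2.2,368,25,
eP3a,Old,DS,Cz,3.6,2.6,368,25,
eP3a,Old,DS,Pz,2.0,2.1,368,25,
lP3a,Young,NS,Fz,11.2,5.3,370,42,
lP3a,Young,NS,Cz,12.7,5.8,370,42,
lP3a,Young,NS,Pz,11.0,4.2,370,42,
lP3a,Young,DS,Fz,3.5,3.2,398,46,
lP3a,Young,DS,Cz,4.0,3.5,398,46,
lP3a,Young,DS,Pz,3.8,2.7,398,46,
lP3a,MiddleAged,NS,Fz,9.2,3.8,451,31,
lP3a,MiddleAged,NS,Cz,11.7,4.1,451,31,
lP3a,MiddleAged,NS,Pz,10.3,4.0,451,31,
lP3a,MiddleAged,DS,Fz,2.4,1.9,455,44,
lP3a,MiddleAged,DS,Cz,3.3,2.4,455,44,
lP3a,MiddleAged,DS,Pz,3.0,2.5,455,44,
lP3a,Old,NS,Fz,9.6,2.7,457,27,
lP3a,Old,NS,Cz,12.2,4.0,457,27,
lP3a,Old,NS,Pz,9.9,4.3,457,27,
lP3a,Old,DS,Fz,2.4,1.8,453,33,
lP3a,Old,DS,Cz,3.5,2.8,453,33,
lP3a,Old,DS,Pz,3.1,2.4,453,33,
RON,Young,NS,Fz,-3.5,3.1,527,95,
RON,Young,NS,Cz,-2.7,3.7,527,95,
RON,Young,DS,Fz,-2.8,1.1,528,84,
RON,Young,DS,Cz,-2.5,1.8,528,84,
RON,MiddleAged,NS,Fz,-2.1,2.3,631,57,
RON,MiddleAged,NS,Cz,-2.8,3.1,631,57,
RON,MiddleAged,DS,Fz,-2.4,2.1,594,55,
RON,MiddleAged,DS,Cz,-2.8,2.2,594,55,
RON,Old,NS,Fz,-2.1,1.8,657,41,
RON,Old,NS,Cz,-1.4,2.5,657,41,
RON,Old,DS,Fz,-2.7,1.6,644,63,
RON,Old,DS,Cz,-2.9,1.9,644,63,sign_corrected
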