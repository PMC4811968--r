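# Idealized unit-sphere scalp coordinates for the default 49-channel 10-10 montage
# (sphere-fitted standard 10-10 positions, nose along +y, vertex at +z) plus 4 periocular EOG sites.
label,x,y,z,type
Fp1,-0.288194,0.950723,-0.114321,scalp
Fp2,0.268437,0.956438,-0.114748,scalp
AF3,-0.343701,0.925682,0.158060,scalp
AF4,0.336909,0.927153,0.163949,scalp
F7,-0.755727,0.630963,-0.175395,scalp
F5,-0.703845,0.699103,0.125928,scalp
F3,-0.543554,0.742715,0.391054,scalp
F1,-0.296705,0.766099,0.570140,scalp
Fz,-0.009282,0.777220,0.629160,scalp
F2,0.292603,0.773509,0.562199,scalp
F4,0.535173,0.756026,0.376849,scalp
F6,0.700432,0.703965,0.117592,scalp
F8,0.746752,0.640701,-0.178504,scalp
FC5,-0.887567,0.405671,0.218301,scalp
FC3,-0.690741,0.449114,0.566722,scalp
FC1,-0.378010,0.463058,0.801676,scalp
FCz,-0.008877,0.471079,0.882047,scalp
FC2,0.365080,0.474652,0.800889,scalp
FC4,0.684930,0.458969,0.565878,scalp
FC6,0.882018,0.418275,0.217004,scalp
T7,-0.985761,0.013691,-0.167594,scalp
C5,-0.958511,0.040515,0.282162,scalp
C3,-0.745889,0.062436,0.663138,scalp
C1,-0.402944,0.077847,0.911908,scalp
Cz,-0.008547,0.084235,0.996409,scalp
C2,0.399772,0.083126,0.912838,scalp
C4,0.746448,0.071406,0.661601,scalp
C6,0.958557,0.051613,0.280186,scalp
T8,0.984740,0.025647,-0.172134,scalp
CP5,-0.900332,-0.326962,0.287224,scalp
CP3,-0.692902,-0.318831,0.646710,scalp
CP1,-0.373406,-0.305880,0.875788,scalp
CPz,-0.008394,-0.304302,0.952539,scalp
CP2,0.379572,-0.305034,0.873430,scalp
CP4,0.697423,-0.313892,0.644262,scalp
CP6,0.903719,-0.318062,0.286580,scalp
P7,-0.792039,-0.604893,-0.082337,scalp
P3,-0.561961,-0.638234,0.526173,scalp
P1,-0.300828,-0.638426,0.708460,scalp
Pz,-0.008881,-0.636464,0.771255,scalp
P2,0.306020,-0.630739,0.713106,scalp
P4,0.562496,-0.633833,0.530899,scalp
P8,0.786594,-0.611673,-0.084414,scalp
PO3,-0.388219,-0.860742,0.329255,scalp
POz,-0.010386,-0.881791,0.471527,scalp
PO4,0.370060,-0.870333,0.324926,scalp
O1,-0.305944,-0.951344,0.036653,scalp
Oz,-0.011297,-0.995253,0.096660,scalp
O2,0.288456,-0.956794,0.036584,scalp
VEOGU,0.259252,0.964417,-0.051850,eog
VEOGL,0.255235,0.898427,-0.357329,eog
HEOGL,-0.754961,0.624101,-0.201323,eog
HEOGR,0.754961,0.624101,-0.201323,eog
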