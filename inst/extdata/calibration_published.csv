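analyte_id,a2,a1,a0,model,internal_standard_id,lod_ng_ml
PFBA,0,0.8092,0.0579,linear,MPFBA,0.6
PFPeA,0,0.3435,0.0068,linear,MPFBA,0.7
PFHxA,0,1.103,0.122,linear,MPFHxA,0.7
PFHpA,0,0.7907,0.0382,linear,MPFHxA,0.6
PFOA,0,1.0968,0.1978,linear,MPFOA,1.0
PFNA,-0.0156,0.953,0.057,quadratic,MPFNA,0.8
PFDA,0,0.9312,0.0197,linear,MPFDA,0.6
PFUdA,0,0.9854,0.039,linear,MPFUdA,0.6
PFDoA,0,0.89,0.0311,linear,MPFDoA,0.5
PFTrDA,0,1.1157,0.008,linear,MPFDoA,0.5
PFTeDA,0,0.8752,0.013,linear,MPFDoA,0.7
PFHxDA,0,0.6599,-0.0098,linear,MPFDoA,0.6
PFODA,0,0.7385,-0.0222,linear,MPFDoA,0.4
L-PFBS,0,9.9377,0.0499,linear,MPFHxS,0.5
L-PFHxS,-0.0538,5.5136,0.0339,quadratic,MPFHxS,0.4
L-PFOS,-0.0165,1.0528,0.045,quadratic,MPFOS,0.4
L-PFDS,-0.018,1.0766,0.018,quadratic,MPFOS,0.8
HFPO-DA,0,0.1406,0.0051,linear,MPFHxA,0.7
ADONA,0,3.236,-0.1108,linear,MPFOA,0.7
9Cl-PF3ONS,0.0144,0.7061,0.0235,quadratic,MPFOS,0.6
11Cl-PF3OUdS,0,0.4769,0.0143,linear,MPFOS,0.7
PF4OPeA,0,0.4607,0.0111,linear,MPFBA,0.5
PF5OHxA,0,1.6888,0.0302,linear,MPFHxA,0.7
PFEESA,0,36.76,0.4631,linear,MPFHxA,0.7
"3,6-OPFHpA",0,0.0356,0.0001,linear,MPFHxS,1.0
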