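specimen_id,condition,lp,thickness_um,k11_m2
B1,baseline,1.35e-10,26.1,4.49e-18
B2,baseline,1.48e-10,28.9,4.50e-18
B3,baseline,1.40e-10,27.2,4.37e-18
B4,baseline,1.50e-10,29.3,4.11e-18
B5,baseline,1.43e-10,27.0,4.17e-18
C1,constricted,0.95e-10,32.4,7.20e-18
C2,constricted,1.02e-10,34.0,6.95e-18
C3,constricted,0.97e-10,32.9,6.95e-18
C4,constricted,1.01e-10,33.5,6.79e-18
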