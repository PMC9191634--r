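peptide,channel,voltage_mV,ki,ki_unit,h,kon,koff,conc,conc_unit
C6,hHv1,0,1.5,nM,1.22,5e5,0.0015,250,nM
C6,hHv1,20,4.9,nM,0.69,4e5,0.0043,250,nM
C6,hHv1,40,31,nM,0.48,3e5,0.022,250,nM
C6_2,hHv1,0,0.041,nM,1.07,1e6,5.7e-5,10,nM
C6_2,hHv1,40,0.63,nM,1.01,9e5,7e-4,10,nM
C6,hHv1-R205N,40,161,nM,0.5,3e5,0.19,250,nM
C6,hHv1-R211S,40,0.6,nM,0.4,5e5,8e-4,250,nM
C6,hHv1-G199C,40,1.9,nM,0.48,NA,NA,NA,nM
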