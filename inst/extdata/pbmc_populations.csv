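name,weight,FSC-A,SSC-A,CD123,CD11c,MHC-II,CD14,IL-6,IL-12,TNF-a,IFN-a,sd,responder_fraction,shift_IL-6,shift_IL-12,shift_TNF-a,shift_IFN-a
debris/dead,0.15,3.00,2.90,1.00,1.00,1.20,1.00,0.80,0.80,0.80,0.80,0.18,0,0,0,0,0
monocytes,0.24,4.55,4.30,1.50,3.20,3.50,4.10,1.20,1.20,1.20,1.20,0.10,0.5,2.2,2.0,2.2,0.5
mDC,0.08,4.40,4.00,1.60,4.10,4.25,1.90,1.20,1.20,1.20,1.20,0.10,0.5,1.8,2.0,1.8,0.6
pDC,0.06,4.30,3.75,4.05,1.50,3.40,1.40,1.10,1.10,1.10,1.10,0.10,0.5,1.0,0.8,1.2,2.4
B cells,0.20,4.35,3.85,1.30,1.40,4.50,1.20,1.00,1.00,1.00,1.00,0.10,0,0,0,0,0
novel-1,0.15,4.50,4.20,2.90,2.90,2.40,2.90,1.00,1.00,1.00,1.00,0.10,0,0,0,0,0
novel-2,0.12,4.30,3.50,1.20,1.20,1.60,1.30,1.00,1.00,1.00,1.00,0.10,0,0,0,0,0
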