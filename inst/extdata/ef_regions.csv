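region,i_ftir,i_seftir,c_ftir,c_seftir
5300,0.72,1.35,1e-2,1e-6
5700,1.76,1.22,1e-2,1e-6
6000,1.43,2.08,1e-2,1e-6
6700,0.51,0.79,1e-2,1e-6
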