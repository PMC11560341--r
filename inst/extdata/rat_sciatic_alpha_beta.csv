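trial,alpha_MPa,beta_MPa
Female 1,0.202,2.04
Female 2,0.305,3.40
Female 3,0.060,0.78
Female 4,0.203,1.09
Male 1,0.310,1.54
Male 2,0.037,2.59
Male 4,0.161,1.74
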