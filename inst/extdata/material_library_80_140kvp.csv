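name,density_g_cm3,mu_low_cm1,mu_high_cm1,group
air,0.001293,0.000263,0.000229,default
water,1,0.222209,0.194798,default
blood,1.06,0.235909,0.207181,default
fat,0.95,0.198112,0.179551,default
bone,1.92,0.763847,0.511092,default
lexan,1.2,0.240811,0.21726,default
acrylic,1.19,0.244138,0.218712,default
teflon,2.2,0.449586,0.400893,default
koh50,1.514,0.419922,0.322894,default
omnipaque350,1.41,4.028523,1.951639,default
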