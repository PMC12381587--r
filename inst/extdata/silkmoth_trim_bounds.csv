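species,parameter,min,max,trim
A_io,f,20,24,21.938
A_io,chi_m,2,24,22.818
A_io,chi_a,7,17,12.768
A_io,beta_m,36,76,60.748
A_io,beta_a,7,18,7.592
A_io,beta_r,0,4,1.461
A_io,phi_m,5,44,37.293
A_io,phi_a,103,149,127.09
A_io,alpha_m,76,88,82.674
A_io,alpha_a,43,71,55.389
A_io,theta_m,-1,1,0.322
A_io,theta_a,13,22,17.838
A_io,kL,0.5,2,1.705
A_io,kD,0.6,1.4,0.6
A_luna,f,13,15,13.011
A_luna,chi_m,-4,27,26.946
A_luna,chi_a,20,27,23.637
A_luna,beta_m,66,82,68.876
A_luna,beta_a,20,26,26.002
A_luna,beta_r,-1,2,-0.99
A_luna,phi_m,7,17,16.424
A_luna,phi_a,124,134,124.076
A_luna,alpha_m,78,85,85.019
A_luna,alpha_a,32,44,43.99
A_luna,theta_m,0,1,0.171
A_luna,theta_a,21,29,21.019
A_luna,kL,0.5,2,1.295
A_luna,kD,0.6,1.4,0.6
A_polyphemus,f,7,13,8.872
A_polyphemus,chi_m,18,21,20.016
A_polyphemus,chi_a,37,51,43.718
A_polyphemus,beta_m,54,68,64.007
A_polyphemus,beta_a,32,57,38.995
A_polyphemus,beta_r,-5,1,-1.388
A_polyphemus,phi_m,26,38,33.461
A_polyphemus,phi_a,119,148,123.126
A_polyphemus,alpha_m,82,89,85.871
A_polyphemus,alpha_a,45,94,45.67
A_polyphemus,theta_m,-1,0,-0.528
A_polyphemus,theta_a,14,38,30.98
A_polyphemus,kL,0.5,2,1.128
A_polyphemus,kD,0.6,1.4,0.609
H_euryalus,f,12,14,12.329
H_euryalus,chi_m,34,53,48.363
H_euryalus,chi_a,15,25,22.428
H_euryalus,beta_m,22,60,44.245
H_euryalus,beta_a,14,28,25.858
H_euryalus,beta_r,-2,1,-1.378
H_euryalus,phi_m,5,40,31.608
H_euryalus,phi_a,100,127,100.296
H_euryalus,alpha_m,82,93,89.384
H_euryalus,alpha_a,29,51,36.175
H_euryalus,theta_m,-1,1,-0.15
H_euryalus,theta_a,12,33,20.715
H_euryalus,kL,0.5,2,1.383
H_euryalus,kD,0.6,1.4,0.612
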