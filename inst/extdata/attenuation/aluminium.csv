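# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients for aluminium, cm^2/g, 10-300 keV.
# Transcribed from the standard published photon cross-section compilations;
# log-log interpolation is intended between grid energies.
energy_kev,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g
10,26.23,25.43
15,7.955,7.487
20,3.442,3.094
30,1.128,0.8778
40,0.5685,0.3601
50,0.3681,0.1840
60,0.2778,0.1099
80,0.2018,0.05511
100,0.1704,0.03794
150,0.1378,0.02827
200,0.1223,0.02745
300,0.1042,0.02816
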