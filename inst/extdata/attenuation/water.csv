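# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients for liquid water, cm^2/g, 10-300 keV.
# Transcribed from the standard published photon cross-section compilations;
# log-log interpolation is intended between grid energies.
energy_kev,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g
10,5.329,4.944
15,1.673,1.374
20,0.8096,0.5503
30,0.3756,0.1557
40,0.2683,0.0695
50,0.2269,0.04223
60,0.2059,0.03190
80,0.1837,0.02597
100,0.1707,0.02546
150,0.1505,0.02764
200,0.1370,0.02967
300,0.1186,0.03192
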