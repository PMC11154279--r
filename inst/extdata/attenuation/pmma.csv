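# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients for polymethyl methacrylate (PMMA), cm^2/g, 10-300 keV.
# Transcribed from the standard published photon cross-section compilations;
# log-log interpolation is intended between grid energies.
energy_kev,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g
10,3.357,3.026
15,1.101,0.8324
20,0.5714,0.3328
30,0.3032,0.09645
40,0.2350,0.04599
50,0.2074,0.03067
60,0.1924,0.02530
80,0.1751,0.02302
100,0.1641,0.02368
150,0.1456,0.02657
200,0.1328,0.02872
300,0.1152,0.03099
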