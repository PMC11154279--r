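# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients for average soft tissue (ICRU four-component style),
# cm^2/g, 10-300 keV.
# Transcribed from the standard published photon cross-section compilations;
# log-log interpolation is intended between grid energies.
energy_kev,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g
10,5.367,4.964
15,1.693,1.396
20,0.8205,0.5641
30,0.3783,0.1610
40,0.2685,0.07184
50,0.2262,0.04340
60,0.2048,0.03258
80,0.1823,0.02615
100,0.1693,0.02544
150,0.1492,0.02745
200,0.1358,0.02942
300,0.1175,0.03164
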