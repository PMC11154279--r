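# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients for tungsten, cm^2/g, 10-300 keV.
# Transcribed from the standard published photon cross-section compilations.
# APPROXIMATE: L-shell edge fine structure (10.2-12.1 keV) is collapsed and
# the K edge (69.5 keV) is represented by a two-point discontinuity; values
# between grid points carry a few-percent transcription uncertainty.  The
# package uses this table for septum transmission/leakage estimates, where
# exp(-mu * 7 mm) is insensitive at this level.
energy_kev,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g
10,96.91,91.00
12.1,193.0,160.0
15,105.0,93.00
20,65.73,57.00
30,22.73,19.70
40,10.67,9.240
50,5.949,5.110
60,3.713,3.170
69.52,2.552,2.160
69.53,11.23,4.900
80,7.810,4.010
100,4.438,2.710
150,1.581,1.093
200,0.7844,0.5960
300,0.3238,0.2730
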