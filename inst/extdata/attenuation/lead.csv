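# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients for lead, cm^2/g, 10-300 keV.
# Transcribed from the standard published photon cross-section compilations.
# APPROXIMATE: L-shell edge fine structure (13.0-15.9 keV) is collapsed and
# the K edge (88.0 keV) is represented by a two-point discontinuity; the
# mu_en column is a coarse estimate.  Lead enters the model only as the
# auxiliary field-reducing aperture, which is treated as opaque, so these
# values only bound its leakage.
energy_kev,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g
10,130.6,104.0
15,111.6,85.00
20,86.36,65.00
30,30.32,25.00
40,14.36,12.00
50,8.041,6.700
60,5.021,4.200
80,2.419,2.000
88,1.910,1.600
88.01,7.683,2.400
100,5.549,2.280
150,2.014,1.056
200,0.9985,0.6300
300,0.4031,0.2600
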