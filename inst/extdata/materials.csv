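# Materials database: nominal mass density, mean Z/A (electrons per amu,
# used for the Klein-Nishina electron density), and the attenuation table
# file shipped with the package.
name,density_g_cm3,z_over_a,table
air,0.0012,0.49919,air.csv
lung,0.26,0.54996,lung.csv
water,1.000,0.55509,water.csv
soft_tissue,1.06,0.54996,soft_tissue.csv
pmma,1.19,0.53937,pmma.csv
bone_cortical,1.92,0.51478,bone_cortical.csv
aluminium,2.699,0.48181,aluminium.csv
tungsten,19.30,0.40252,tungsten.csv
lead,11.35,0.39575,lead.csv
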