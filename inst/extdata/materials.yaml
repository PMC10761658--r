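# Built-in material library for Lu-177 multi-photopeak quantification.
# mass_attenuation entries are mu/rho in cm^2/g at the three photopeak
# energies (keV keys), density in g/cm^3.
#
# PMMA is pinned to the printed calibration parametrization for this camera
# (rho = 1.18 g/cm^3; mu/rho = 0.20 / 0.16 / 0.13 cm^2/g at 55 / 113 / 208
# keV). Water, soft tissue and cortical bone are log-log interpolations of
# the NIST / ICRU-44 mass-attenuation tables at 55, 113 and 208 keV.
pmma:
  density: 1.18
  mass_attenuation:
    "55": 0.20
    "113": 0.16
    "208": 0.13
water:
  density: 0.998
  mass_attenuation:
    "55": 0.2155
    "113": 0.1650
    "208": 0.1354
soft_tissue:
  density: 1.06
  mass_attenuation:
    "55": 0.2105
    "113": 0.1625
    "208": 0.1333
cortical_bone:
  density: 1.92
  mass_attenuation:
    "55": 0.3650
    "113": 0.1755
    "208": 0.1289
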