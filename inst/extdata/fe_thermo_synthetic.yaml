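# Synthetic placeholder thermodynamic dataset for Fe(III) in seawater.
# Reference temperature 298.15 K; enthalpies in J mol-1; constants on the
# activity scale for a simple electrolyte medium (applied at seawater ionic
# strength through the Davies equation). These are order-of-magnitude
# literature-style values assembled for this package, NOT a critically
# reviewed compilation: replace with a calibrated deck before quantitative
# use against field data.
activity_model: davies
components:
  - {name: fe3, charge: 3}
  - {name: h,   charge: 1}
  - {name: mg,  charge: 2}
  - {name: ca,  charge: 2}
  - {name: na,  charge: 1}
  - {name: k,   charge: 1}
  - {name: cl,  charge: -1}
  - {name: so4, charge: -2}
reactions:
  # Fe3+ + n H2O = Fe(OH)n^(3-n) + n H+   (water implicit)
  - {product: feoh2p,  charge: 2,  logk_ref: -2.19,  delta_h: 30000,
     stoich: {fe3: 1, h: -1}}
  - {product: feoh2_p, charge: 1,  logk_ref: -5.60,  delta_h: 50000,
     stoich: {fe3: 1, h: -2}}
  - {product: feoh3_0, charge: 0,  logk_ref: -11.90, delta_h: 65000,
     stoich: {fe3: 1, h: -3}}
  - {product: feoh4_m, charge: -1, logk_ref: -22.30, delta_h: 80000,
     stoich: {fe3: 1, h: -4}}
mineral:
  # Fe(OH)3(s) + 3 H+ = Fe3+ + 3 H2O (dissolution); exothermic, so the
  # solubility of Fe' increases as temperature decreases.
  name: authFeOH
  # enthalpy chosen so that the overall solid -> Fe' dissolution (cap
  # reaction plus hydrolysis) is exothermic and Fe' solubility increases as
  # temperature decreases
  logks_ref: 2.48
  delta_h: -100000
  medium: "synthetic placeholder; styled after constants derived in sodium chloride media"
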