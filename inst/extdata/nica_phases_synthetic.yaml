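# Synthetic placeholder NICA-Donnan parameter sets for marine dissolved and
# particulate organic matter. Layout mirrors a typical speciation-program
# input deck: per phase, a Donnan volume parameter and two binding site
# groups (1: carboxylic-type low affinity, 2: phenolic-type high affinity),
# each with site density qmax (mol kg-1), median proton affinity logk_h,
# proton non-ideality n_h, generic heterogeneity p, and per-ion median
# affinities/non-idealities.
#
# The DOM set is fulvic-acid-shaped with Fe parameters tuned once so that,
# at open-ocean conditions (DFe ~ 0.2-2 nmol/L, DOC ~ 40 umol/L, pH_tot
# 7.5-8.0), most dissolved Fe is DOM-bound, Fe' falls in the 0.05-1 nmol/L
# range, and weighted mean effective affinities of occupied sites span
# log K' ~ 16-24. The POM set keeps the generic humic-acid shape but with
# total site density reduced to 1 mol kg-1 split 3:1 between the low- and
# high-affinity groups, and Fe affinities ~1.7 log units above DOM.
# All values are hypothetical placeholders pending experimental calibration.
dom:
  donnan_b: 0.57
  groups:
    - qmax: 5.88
      logk_h: 2.93
      n_h: 0.66
      p: 0.59
      ions:
        mg: {logk: 1.00, "n": 0.77}
        ca: {logk: 1.20, "n": 0.78}
        fe: {logk: 7.20, "n": 0.30}
    - qmax: 1.86
      logk_h: 8.00
      n_h: 0.76
      p: 0.70
      ions:
        mg: {logk: 0.70, "n": 0.59}
        ca: {logk: 1.40, "n": 0.75}
        fe: {logk: 7.40, "n": 0.25}
pom:
  donnan_b: 0.49
  groups:
    - qmax: 0.75
      logk_h: 2.93
      n_h: 0.81
      p: 0.62
      ions:
        mg: {logk: 0.80, "n": 0.75}
        ca: {logk: 1.60, "n": 0.78}
        fe: {logk: 14.50, "n": 0.15}
    - qmax: 0.25
      logk_h: 8.00
      n_h: 0.63
      p: 0.41
      ions:
        mg: {logk: 0.60, "n": 0.70}
        ca: {logk: 1.00, "n": 0.70}
        fe: {logk: 16.50, "n": 0.12}
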