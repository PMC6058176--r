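# National scale-up scenario: the trial's utilisation effects applied to a
# Burkina Faso national mortality envelope, 2012-2014, with a penetration
# index rescaling impact from trial-zone radio listenership (52%) to the
# national level (45.2%).
#
# Mortality rates, utilisation effects, receipt proportions, effectiveness
# values, affected fractions and penetration proportions are the published
# trial inputs. Live births and the cause-of-death fractions are SYNTHETIC
# stand-ins for the Spectrum/LiST base projection for Burkina Faso, which is
# not redistributable here. Baseline coverages are illustrative.
name: national
envelope:
  years: [2012, 2013, 2014]
  u5mr: [103.3, 97.7, 92.8]        # national IGME-style rates
  live_births: [700000, 710000, 720000]  # synthetic national live births
  cause_fractions:                  # synthetic WHO-2011-style structure
    malaria: 0.22
    pneumonia: 0.15
    diarrhoea: 0.08
    neonatal: 0.30
population_scale: 1
population_scale_mode: births
penetration:
  reference: 0.52    # female radio listenership, trial intervention zones
  target: 0.452      # national female radio listenership
interventions:
  - name: act_malaria
    effectiveness: 0.87             # conservative ACT effectiveness
    affected_fraction: 1.0
    causes: [malaria]
    coverage_mode: treatment_with_receipt
    receipt: 0.543                  # fever attenders receiving an antimalarial
    baseline_coverage: 0.30         # illustrative DHS-2010-style value
    effect_source: malaria
    effects:                        # relative utilisation increases, years 1-3
      - {point: 0.56, low: 0.30, high: 0.88}
      - {point: 0.37, low: 0.12, high: 0.69}
      - {point: 0.35, low: 0.09, high: 0.67}
  - name: pneumonia_antibiotics
    effectiveness: 0.70
    affected_fraction: 1.0
    causes: [pneumonia]
    coverage_mode: careseeking_proxy   # care-seeking proxies antibiotic receipt
    baseline_coverage: 0.35         # illustrative
    effect_source: lrti
    effects:
      - {point: 0.39, low: 0.22, high: 0.58}
      - {point: 0.25, low: 0.05, high: 0.49}
      - {point: 0.11, low: -0.20, high: 0.54}
  - name: ors_diarrhoea
    effectiveness: 0.93
    affected_fraction: 1.0
    causes: [diarrhoea]
    coverage_mode: treatment_with_receipt
    receipt: 0.345                  # diarrhoea attenders receiving ORS
    baseline_coverage: 0.25         # illustrative
    effect_source: diarrhoea
    effects:
      - {point: 0.73, low: 0.42, high: 1.10}
      - {point: 0.60, low: 0.12, high: 1.29}
      - {point: 1.07, low: 0.43, high: 2.00}
  - name: anc_bundle
    # tetanus toxoid + IPTp + syphilis detection sharing the ANC coverage
    # path; effectiveness here is a single illustrative bundle value, NOT a
    # LiST default.
    effectiveness: 0.05
    affected_fraction: 1.0
    causes: [neonatal]
    coverage_mode: direct
    baseline_coverage: 0.60         # illustrative
    effects:                        # ANC attendance effects; no CIs published
      - {point: 0.06, low: 0.06, high: 0.06}
      - {point: 0.09, low: 0.09, high: 0.09}
      - {point: 0.08, low: 0.08, high: 0.08}
  - name: facility_delivery
    effectiveness: 0.10             # illustrative bundle value, NOT a LiST default
    affected_fraction: 1.0
    causes: [neonatal]
    coverage_mode: direct
    baseline_coverage: 0.45         # illustrative
    effects:
      - {point: 0.07, low: 0.07, high: 0.07}
      - {point: 0.06, low: 0.06, high: 0.06}
      - {point: 0.09, low: 0.09, high: 0.09}
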