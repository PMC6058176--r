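# Trial-zone scenario: campaign effect on under-five mortality in the seven
# intervention clusters, 2012-2014.
#
# Mortality rates, utilisation effects, receipt proportions, effectiveness
# values and affected fractions are the published trial inputs. Live births
# and the cause-of-death fractions are SYNTHETIC stand-ins: the originals
# live in the Spectrum/LiST base projection for Burkina Faso (DHS 2010 +
# WHO 2011 cause structure), which is not redistributable here. Baseline
# treatment coverages are likewise illustrative DHS-2010-style values.
name: trial_zone
envelope:
  years: [2012, 2013, 2014]
  u5mr: [137.0, 126.5, 105.1]       # deaths per 1000 live births, intervention arm
  live_births: [112000, 113000, 114000]   # synthetic: ~2.4 M population zones
  cause_fractions:                  # synthetic WHO-2011-style structure
    malaria: 0.22
    pneumonia: 0.15
    diarrhoea: 0.08
    neonatal: 0.30
population_scale: 1
population_scale_mode: births
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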