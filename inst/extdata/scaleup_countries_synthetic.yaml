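# Five-country national media-campaign scale-up scenarios, 2018-2020, in the
# shape of a multi-country projection table (lives saved per year under 0%,
# 10% and 20% discounting).
#
# The utilisation effects (with confidence bounds), receipt proportions and
# treatment effectiveness values are the published trial inputs, reused in
# every country. Every country-specific quantity in this file is a SYNTHETIC
# illustrative stand-in: mortality rates, live births, cause-of-death
# fractions, baseline coverages and media-penetration proportions. The
# published per-country values live in the trial's supplementary material and
# the Spectrum/LiST country files, neither redistributable here.
countries:
  - name: burkina_faso
    envelope:
      years: [2018, 2019, 2020]
      u5mr: [81.6, 78.4, 75.3]
      live_births: [780000, 790000, 800000]
      cause_fractions:
        malaria: 0.22
        pneumonia: 0.15
        diarrhoea: 0.08
    penetration:
      reference: 0.52
      target: 0.452
    interventions:
      - name: act_malaria
        effectiveness: 0.87
        affected_fraction: 1.0
        causes: [malaria]
        coverage_mode: treatment_with_receipt
        receipt: 0.543
        baseline_coverage: 0.30
        effects:
          - {point: 0.56, low: 0.30, high: 0.88}
          - {point: 0.37, low: 0.12, high: 0.69}
          - {point: 0.35, low: 0.09, high: 0.67}
      - name: pneumonia_antibiotics
        effectiveness: 0.70
        affected_fraction: 1.0
        causes: [pneumonia]
        coverage_mode: careseeking_proxy
        baseline_coverage: 0.35
        effects:
          - {point: 0.39, low: 0.22, high: 0.58}
          - {point: 0.25, low: 0.05, high: 0.49}
          - {point: 0.11, low: -0.20, high: 0.54}
      - name: ors_diarrhoea
        effectiveness: 0.93
        affected_fraction: 1.0
        causes: [diarrhoea]
        coverage_mode: treatment_with_receipt
        receipt: 0.345
        baseline_coverage: 0.25
        effects:
          - {point: 0.73, low: 0.42, high: 1.10}
          - {point: 0.60, low: 0.12, high: 1.29}
          - {point: 1.07, low: 0.43, high: 2.00}
  - name: burundi
    envelope:
      years: [2018, 2019, 2020]
      u5mr: [58.5, 56.1, 54.0]
      live_births: [440000, 450000, 460000]
      cause_fractions:
        malaria: 0.22
        pneumonia: 0.15
        diarrhoea: 0.08
    penetration:
      reference: 0.52
      target: 0.55
    interventions:
      - name: act_malaria
        effectiveness: 0.87
        affected_fraction: 1.0
        causes: [malaria]
        coverage_mode: treatment_with_receipt
        receipt: 0.543
        baseline_coverage: 0.30
        effects:
          - {point: 0.56, low: 0.30, high: 0.88}
          - {point: 0.37, low: 0.12, high: 0.69}
          - {point: 0.35, low: 0.09, high: 0.67}
      - name: pneumonia_antibiotics
        effectiveness: 0.70
        affected_fraction: 1.0
        causes: [pneumonia]
        coverage_mode: careseeking_proxy
        baseline_coverage: 0.35
        effects:
          - {point: 0.39, low: 0.22, high: 0.58}
          - {point: 0.25, low: 0.05, high: 0.49}
          - {point: 0.11, low: -0.20, high: 0.54}
      - name: ors_diarrhoea
        effectiveness: 0.93
        affected_fraction: 1.0
        causes: [diarrhoea]
        coverage_mode: treatment_with_receipt
        receipt: 0.345
        baseline_coverage: 0.25
        effects:
          - {point: 0.73, low: 0.42, high: 1.10}
          - {point: 0.60, low: 0.12, high: 1.29}
          - {point: 1.07, low: 0.43, high: 2.00}
  - name: malawi
    envelope:
      years: [2018, 2019, 2020]
      u5mr: [49.7, 47.6, 45.7]
      live_births: [660000, 670000, 680000]
      cause_fractions:
        malaria: 0.22
        pneumonia: 0.15
        diarrhoea: 0.08
    penetration:
      reference: 0.52
      target: 0.6
    interventions:
      - name: act_malaria
        effectiveness: 0.87
        affected_fraction: 1.0
        causes: [malaria]
        coverage_mode: treatment_with_receipt
        receipt: 0.543
        baseline_coverage: 0.30
        effects:
          - {point: 0.56, low: 0.30, high: 0.88}
          - {point: 0.37, low: 0.12, high: 0.69}
          - {point: 0.35, low: 0.09, high: 0.67}
      - name: pneumonia_antibiotics
        effectiveness: 0.70
        affected_fraction: 1.0
        causes: [pneumonia]
        coverage_mode: careseeking_proxy
        baseline_coverage: 0.35
        effects:
          - {point: 0.39, low: 0.22, high: 0.58}
          - {point: 0.25, low: 0.05, high: 0.49}
          - {point: 0.11, low: -0.20, high: 0.54}
      - name: ors_diarrhoea
        effectiveness: 0.93
        affected_fraction: 1.0
        causes: [diarrhoea]
        coverage_mode: treatment_with_receipt
        receipt: 0.345
        baseline_coverage: 0.25
        effects:
          - {point: 0.73, low: 0.42, high: 1.10}
          - {point: 0.60, low: 0.12, high: 1.29}
          - {point: 1.07, low: 0.43, high: 2.00}
  - name: mozambique
    envelope:
      years: [2018, 2019, 2020]
      u5mr: [72.4, 69.5, 66.8]
      live_births: [1150000, 1170000, 1190000]
      cause_fractions:
        malaria: 0.22
        pneumonia: 0.15
        diarrhoea: 0.08
    penetration:
      reference: 0.52
      target: 0.5
    interventions:
      - name: act_malaria
        effectiveness: 0.87
        affected_fraction: 1.0
        causes: [malaria]
        coverage_mode: treatment_with_receipt
        receipt: 0.543
        baseline_coverage: 0.30
        effects:
          - {point: 0.56, low: 0.30, high: 0.88}
          - {point: 0.37, low: 0.12, high: 0.69}
          - {point: 0.35, low: 0.09, high: 0.67}
      - name: pneumonia_antibiotics
        effectiveness: 0.70
        affected_fraction: 1.0
        causes: [pneumonia]
        coverage_mode: careseeking_proxy
        baseline_coverage: 0.35
        effects:
          - {point: 0.39, low: 0.22, high: 0.58}
          - {point: 0.25, low: 0.05, high: 0.49}
          - {point: 0.11, low: -0.20, high: 0.54}
      - name: ors_diarrhoea
        effectiveness: 0.93
        affected_fraction: 1.0
        causes: [diarrhoea]
        coverage_mode: treatment_with_receipt
        receipt: 0.345
        baseline_coverage: 0.25
        effects:
          - {point: 0.73, low: 0.42, high: 1.10}
          - {point: 0.60, low: 0.12, high: 1.29}
          - {point: 1.07, low: 0.43, high: 2.00}
  - name: niger
    envelope:
      years: [2018, 2019, 2020]
      u5mr: [84.5, 80.9, 77.5]
      live_births: [1000000, 1030000, 1060000]
      cause_fractions:
        malaria: 0.22
        pneumonia: 0.15
        diarrhoea: 0.08
    penetration:
      reference: 0.52
      target: 0.4
    interventions:
      - name: act_malaria
        effectiveness: 0.87
        affected_fraction: 1.0
        causes: [malaria]
        coverage_mode: treatment_with_receipt
        receipt: 0.543
        baseline_coverage: 0.30
        effects:
          - {point: 0.56, low: 0.30, high: 0.88}
          - {point: 0.37, low: 0.12, high: 0.69}
          - {point: 0.35, low: 0.09, high: 0.67}
      - name: pneumonia_antibiotics
        effectiveness: 0.70
        affected_fraction: 1.0
        causes: [pneumonia]
        coverage_mode: careseeking_proxy
        baseline_coverage: 0.35
        effects:
          - {point: 0.39, low: 0.22, high: 0.58}
          - {point: 0.25, low: 0.05, high: 0.49}
          - {point: 0.11, low: -0.20, high: 0.54}
      - name: ors_diarrhoea
        effectiveness: 0.93
        affected_fraction: 1.0
        causes: [diarrhoea]
        coverage_mode: treatment_with_receipt
        receipt: 0.345
        baseline_coverage: 0.25
        effects:
          - {point: 0.73, low: 0.42, high: 1.10}
          - {point: 0.60, low: 0.12, high: 1.29}
          - {point: 1.07, low: 0.43, high: 2.00}
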