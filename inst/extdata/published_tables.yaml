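# Published scenario outputs from the Burkina Faso mass-radio trial,
# 2012-2014 (and 2018-2020 five-country projections), used as INPUTS to the
# scenario algebra: per-year undiscounted under-five lives saved and
# percentage mortality reductions as printed, from which penetration,
# discounting and deaths-weighted averages are recomputed.
trial_zone:
  years: [2012, 2013, 2014]
  lives: [1491, 817, 658]
  lives_low: [777, 95, 239]
  lives_high: [2307, 1880, 1554]
  pct: [9.7, 5.7, 5.5]
  average_reduction: 7.1
national:
  years: [2012, 2013, 2014]
  lives: [6690, 4143, 4055]
  lives_low: [3413, 336, 1083]
  lives_high: [10288, 9413, 10731]
  pct: [9.2, 5.6, 5.5]
  average_reduction: 6.8
  total: 14888
  total_10pct_discount: 13400
  total_20pct_discount: 11910
penetration:
  reference: 0.52
  target: 0.452
  pct_reduction: 13.1
scaleup:                       # undiscounted lives saved (pct reduction)
  years: [2018, 2019, 2020]
  burkina_faso: {lives: [4714, 2851, 2469], pct: [7.7, 4.6, 3.9]}
  burundi:      {lives: [3171, 1847, 2187], pct: [9.8, 5.5, 6.4]}
  malawi:       {lives: [7384, 5664, 6649], pct: [20.7, 15.5, 17.9]}
  mozambique:   {lives: [8519, 4777, 8147], pct: [10.9, 6.0, 10.0]}
  niger:        {lives: [6031, 3142, 4391], pct: [6.7, 3.4, 4.6]}
  # printed discounted cells, for comparison against recomputation
  discounted_10:
    burkina_faso: [4242, 2566, 2223]
    burundi:      [2854, 1662, 1969]
    malawi:       [6645, 5097, 5984]
    mozambique:   [7667, 4299, 7333]
    niger:        [5428, 2828, 3952]
  discounted_20:
    burkina_faso: [3771, 2281, 1976]
    burundi:      [2537, 1478, 1750]
    malawi:       [5907, 4531, 5319]
    mozambique:   [6815, 3822, 6518]
    niger:        [4825, 2513, 3513]
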