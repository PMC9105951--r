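# Model parameter configuration (documented defaults; all fields optional)
ida_share: 0.46
discount_rate: 0.03
income_growth: 0.04
exposure_years: 1.5
life_expectancy: 71
exchange_rate_idr_per_usd: 14582
mean_monthly_wage_idr: 2700000
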