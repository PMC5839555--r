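# Representative days of use per year for each interview frequency
# category. Interview instruments record categories; exposure arithmetic
# and simulation need days/year. Editable configuration, not code.
frequency_days:
  daily: 365
  weekly_not_daily: 104
  two_three_per_month: 30
  less_often: 12
  none: 0
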