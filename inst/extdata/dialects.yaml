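# Frequency-category vocabularies and their servings/day equivalents.
child:
  categories:
    - never
    - sometimes
    - once a day
    - more than once per day
  servings_per_day: [0, 0.5, 1, 2]
adult:
  categories:
    - never
    - sometimes but not weekly
    - weekly
    - every day
    - more than once per day
  servings_per_day: [0, 0.033, 0.143, 1, 2]
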