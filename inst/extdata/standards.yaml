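# AHEI component scoring standards: servings/day mapped to score 0 and
# score 10; reverse components score 10 at zero intake.
- component: vegetables
  direction: positive
  zero_score_servings: 0
  full_score_servings: 5
- component: fruit
  direction: positive
  zero_score_servings: 0
  full_score_servings: 4
- component: whole_grains
  direction: positive
  zero_score_servings: 0
  full_score_servings: 1.5
- component: nuts_legumes
  direction: positive
  zero_score_servings: 0
  full_score_servings: 1
- component: ssb_juice
  direction: reverse
  zero_score_servings: 1
  full_score_servings: 0
- component: red_processed_meat
  direction: reverse
  zero_score_servings: 1.5
  full_score_servings: 0
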