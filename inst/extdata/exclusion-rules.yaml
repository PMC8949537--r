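# Default admissible ranges and exclusion flags for cohort preprocessing.
# These are configuration, not constants: set them to the ranges your
# cohort's data managers recommend. flag_value drops rows whose variable
# equals that value (e.g. supplement users).
rules:
  - variable: bmi
    min: 15
    max: 60
  - variable: tei_kcal
    min: 500
    max: 6000
  - variable: pa_index
    min: 1
    max: 4
  - variable: leisure_exercise
    min: 1
    max: 5
  - variable: supplement_user
    flag_value: 1
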