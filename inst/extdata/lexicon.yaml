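case_sensitive: false
terms:
  - surface: marijuana
    enabled: true
    note: most frequent term for marijuana use in progress notes
  - surface: cannabis
    enabled: true
    note: clinical synonym, frequent in progress notes
  - surface: mjx
    enabled: true
    note: progress-note abbreviation for marijuana
  - surface: mj
    enabled: false
    note: >-
      discarded: overlaps with abbreviations for temporomandibular joint
      (TMJ); kept disabled so the decision is auditable and reversible
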