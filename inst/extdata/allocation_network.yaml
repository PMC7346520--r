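# Scarce-drug allocation network: 3 paradigm clusters, 8 need indicators,
# one allocation goal. The dependency list is a plausible reconstruction of
# the study's network diagram: the goal influences every paradigm cluster,
# the one explicitly named outer arrow runs from Efficiency toward
# Equity and Access, and each cluster carries inner dependence among its own
# indicators. The exact edge set behind the original 45-item questionnaire
# is not recoverable from the published description.
goal: scarce_drug_allocation
clusters:
  - name: Efficiency
    elements: [total_population, non_resident_patients]
  - name: Equity and Access
    elements: [health_professionals, bed_occupancy_rate, prescriptions]
  - name: Effectiveness
    elements: [burden_endemic_diseases, burden_rare_incurable_diseases, burden_traumatic_diseases]
dependencies:
  - {source: scarce_drug_allocation, target: Efficiency, kind: outer}
  - {source: scarce_drug_allocation, target: Equity and Access, kind: outer}
  - {source: scarce_drug_allocation, target: Effectiveness, kind: outer}
  - {source: Efficiency, target: Equity and Access, kind: outer}
  - {source: Efficiency, target: Efficiency, kind: inner}
  - {source: Equity and Access, target: Equity and Access, kind: inner}
  - {source: Effectiveness, target: Effectiveness, kind: inner}
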