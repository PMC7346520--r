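cluster,element,within_cluster_weight,overall_weight,cluster_weight,cluster_rank
Efficiency,total_population,0.6942,0.211,0.370,2
Efficiency,non_resident_patients,0.3065,0.075,0.370,2
Equity and Access,health_professionals,0.1727,0.046,0.459,1
Equity and Access,bed_occupancy_rate,0.3833,0.190,0.459,1
Equity and Access,prescriptions,0.4451,0.262,0.459,1
Effectiveness,burden_endemic_diseases,0.3418,0.053,0.171,3
Effectiveness,burden_rare_incurable_diseases,0.3754,0.077,0.171,3
Effectiveness,burden_traumatic_diseases,0.2846,0.068,0.171,3
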