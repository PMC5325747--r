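horizon_years: 7.0
recurrence_time_years: 2.5
max_additional_procedures: 2
retreat_utility_multiplier: 0.915
post_recurrence_untreated_level: III
post_recurrence_pre_treatment_level: IV_V
psa_outer: 100
psa_inner: 100
seed: 1
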