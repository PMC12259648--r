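# Previously reported summary statistics for the 212579 variant panel,
# used by the report stage for discrepancy flags and fold-change context.
mann_whitney_p_25C_rh: 0.015
kd_fold_uca_vs_parental: 27
kdiss_fold_e38s_vs_parental: 20
kd_fold_light_triple_vs_parental: 4.7
tm_shift_range_C: [2.4, 4.1]
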