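# Default integer scoring map for the heart-failure patient severity index.
# Points accumulate over six components (BUN, BNP, NYHA >= 3, diabetes,
# AF/flutter history, hospitalization in the prior 6 months) and the total
# is cut onto the ordinal 1-4 severity classes. This map is an editable
# stand-in: any monotone component scoring can be supplied in its place.
bun_breaks: [20, 30, 40]      # mg/dL -> 0..3 points
bnp_breaks: [400, 900, 1500]  # pg/mL -> 0..3 points
nyha_ge3_points: 1
diabetes_points: 1
af_flutter_points: 1
recent_hosp_points: 1
class_cuts: [2, 4, 6]         # total 0-1 -> 1, 2-3 -> 2, 4-5 -> 3, >=6 -> 4
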