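# GDMT formulary: guideline target daily doses (mg/day) and titration steps.
# Classes: RASI (subtypes ACEI/ARB/ARNI), BETA_BLOCKER, MRA, SGLT2I.
# Editable: scoring treats this file as configuration, not as fixed truth.
drugs:
  - drug: lisinopril
    class: RASI
    subtype: ACEI
    target_daily_mg: 40
    steps: [5, 10, 20, 40]
  - drug: enalapril
    class: RASI
    subtype: ACEI
    target_daily_mg: 40
    steps: [5, 10, 20, 40]
  - drug: losartan
    class: RASI
    subtype: ARB
    target_daily_mg: 150
    steps: [25, 50, 100, 150]
  - drug: valsartan
    class: RASI
    subtype: ARB
    target_daily_mg: 320
    steps: [80, 160, 320]
  - drug: sacubitril-valsartan
    class: RASI
    subtype: ARNI
    target_daily_mg: 400
    steps: [100, 200, 400]
    # fixed-ratio combination; component targets 194 mg sacubitril +
    # 206 mg valsartan per day (97/103 mg twice daily)
    components:
      sacubitril: 0.485
      valsartan: 0.515
  - drug: carvedilol
    class: BETA_BLOCKER
    subtype: none
    target_daily_mg: 50
    steps: [6.25, 12.5, 25, 50]
  - drug: metoprolol-succinate
    class: BETA_BLOCKER
    subtype: none
    target_daily_mg: 200
    steps: [25, 50, 100, 200]
  - drug: bisoprolol
    class: BETA_BLOCKER
    subtype: none
    target_daily_mg: 10
    steps: [1.25, 2.5, 5, 10]
  - drug: spironolactone
    class: MRA
    subtype: none
    target_daily_mg: 25
    steps: [12.5, 25]
  - drug: eplerenone
    class: MRA
    subtype: none
    target_daily_mg: 50
    steps: [25, 50]
  - drug: dapagliflozin
    class: SGLT2I
    subtype: none
    target_daily_mg: 10
    steps: [5, 10]
  - drug: empagliflozin
    class: SGLT2I
    subtype: none
    target_daily_mg: 10
    steps: [10]
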