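# Eligibility rules gating MOS scoring.
# Variables: sbp (mmHg), pulse (bpm), k (mmol/L), egfr (mL/min/1.73m2),
# scr (mg/dL). Ops: lt / gt (strict).
# contraindication: blocks the class entirely (removed from MOS denominator).
# escalation_block: blocks up-titration of an already-prescribed class
# (current dose earns full credit).
contraindication:
  MRA:
    - {var: k, op: gt, value: 5.0, reason: "K+ > 5.0 mmol/L"}
    - {var: egfr, op: lt, value: 30, reason: "eGFR < 30"}
  SGLT2I:
    - {var: egfr, op: lt, value: 20, reason: "eGFR < 20"}
  RASI:
    - {var: k, op: gt, value: 5.5, reason: "K+ > 5.5 mmol/L"}
    - {var: sbp, op: lt, value: 90, reason: "SBP < 90 mmHg"}
  BETA_BLOCKER:
    - {var: pulse, op: lt, value: 55, reason: "pulse < 55 bpm"}
escalation_block:
  RASI:
    - {var: sbp, op: lt, value: 95, reason: "SBP < 95 mmHg"}
  BETA_BLOCKER:
    - {var: sbp, op: lt, value: 95, reason: "SBP < 95 mmHg"}
    - {var: pulse, op: lt, value: 60, reason: "pulse < 60 bpm"}
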