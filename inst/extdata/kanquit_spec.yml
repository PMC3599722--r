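# KanQuit-style model specification
abstinence: [MDM, HDM, male, cpd, motivation, confidence, sqa]
relapse: [time3, time4, MDM, HDM, income_gt40k, dep5min]
missing: [r_prev, y_prev, y_curr]
time_ref: 1
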