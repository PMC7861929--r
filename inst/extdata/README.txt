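Reference regression fixtures: published four-class (N/S/V/F) KNN benchmark
results on the MIT-BIH arrhythmia database, used as golden tests for the
confusion-matrix metric calculus.

ref_confusions.csv  - confusion matrices for KNN runs with single feature
                      groups (morph, inter, amp) and their combinations.
ref_metrics.csv     - the corresponding per-class Se/Sp/+p/Acc table.  Four
                      cells of the published table are inconsistent with the
                      published confusion matrices themselves and are stored
                      here as recomputed: amp Se_S 1.92 (printed 19.20) and
                      amp Se_F 1.28 (printed 12.80) are decimal-shift
                      misprints; morph_inter Sp_V 99.80 (printed 99.79) and
                      morph_inter Acc_F 99.75 (printed 99.76) are one-ulp
                      rounding slips.
ref_overall.csv     - overall (trace/total) accuracy per block.
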