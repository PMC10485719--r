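participant,algorithm_accuracy,t1_accuracy,t1_confidence,t1_confidence_correct,t1_confidence_incorrect,t2_accuracy,t2_confidence,t2_confidence_correct,t2_confidence_incorrect
Dermatologist,89,85,3.38,3.48,2.80,92,4.09,4.17,3.13
Resident 1,90,44,2.92,3.45,2.50,84,4.00,4.12,3.38
Resident 2,89,60,2.43,2.92,1.70,74,2.85,3.31,1.54
Resident 3,92,80,2.51,2.60,2.15,96,3.45,3.51,2.00
Resident 4,89,62,2.70,2.97,2.26,88,4.41,4.56,3.33
Resident 5,86,66,4.05,4.32,3.53,83,4.46,4.62,3.65
Resident 6,92,65,3.84,3.93,3.66,79,4.06,4.19,3.57
Resident 7,93,60,3.14,3.40,2.75,89,4.00,4.12,3.00
Resident 8,88,38,3.04,3.03,3.05,79,3.38,3.56,2.71
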