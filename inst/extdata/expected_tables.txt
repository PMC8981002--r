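== Fall detection (TP 174, FP 3, FN 52, TN 265) ==
Statistic (95% CI)                Value
Sensitivity (%)                   76.99 (70.95-82.31)
Specificity (%)                   98.88 (96.76-99.77)
Positive likelihood ratio         68.78 (22.27-212.39)
Negative likelihood ratio         0.23 (0.18-0.30)
Positive predictive value (%)     98.31 (94.95-99.44)
Negative predictive value (%)     83.60 (80.05-86.61)
Accuracy (%)                      88.87 (85.76-91.50)
False-positive rate (%)           1.7
False-negative rate (%)           16.4

== Near-fall detection (TP 206, FP 0, FN 43, TN 343) ==
Statistic (95% CI)                Value
Sensitivity (%)                   82.73 (77.45-87.21)
Specificity (%)                   100.00 (98.93-100.00)
Positive likelihood ratio         N/A, undefined (no false positives)
Negative likelihood ratio         0.17 (0.13-0.23)
Positive predictive value (%)     100.00
Negative predictive value (%)     88.86 (85.87-91.28)
Accuracy (%)                      92.74 (90.34-94.69)
False-positive rate (%)           0.0
False-negative rate (%)           11.1

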