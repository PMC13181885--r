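variable,year,treatment,mean,se
pH,2022,NPK,8.72,0.01
pH,2022,CM,8.60,0.02
pH,2022,PM,8.64,0.02
pH,2022,SM,8.67,0.03
pH,2023,NPK,8.29,0.02
pH,2023,CM,8.03,0.01
pH,2023,PM,8.14,0.02
pH,2023,SM,8.16,0.04
SP,2022,NPK,48.20,0.43
SP,2022,CM,49.65,0.92
SP,2022,PM,50.28,0.36
SP,2022,SM,49.91,0.70
SP,2023,NPK,47.71,0.26
SP,2023,CM,49.95,0.43
SP,2023,PM,51.33,0.36
SP,2023,SM,50.35,0.76
TC,2022,NPK,9.62,0.17
TC,2022,CM,10.20,0.17
TC,2022,PM,10.43,0.06
TC,2022,SM,10.71,0.18
TC,2023,NPK,9.55,0.10
TC,2023,CM,10.22,0.34
TC,2023,PM,10.53,0.24
TC,2023,SM,10.90,0.17
TN,2022,NPK,1.60,0.01
TN,2022,CM,1.79,0.11
TN,2022,PM,1.83,0.11
TN,2022,SM,1.81,0.08
TN,2023,NPK,1.63,0.05
TN,2023,CM,1.83,0.02
TN,2023,PM,1.90,0.02
TN,2023,SM,1.87,0.15
TP,2022,NPK,1.49,0.01
TP,2022,CM,1.62,0.03
TP,2022,PM,1.79,0.03
TP,2022,SM,1.88,0.01
TP,2023,NPK,1.53,0.03
TP,2023,CM,1.74,0.04
TP,2023,PM,1.90,0.07
TP,2023,SM,2.04,0.14
TK,2022,NPK,12.17,0.35
TK,2022,CM,13.36,0.45
TK,2022,PM,12.64,0.15
TK,2022,SM,12.70,0.33
TK,2023,NPK,12.37,0.48
TK,2023,CM,13.63,0.22
TK,2023,PM,13.28,0.60
TK,2023,SM,13.33,0.12
NH4,2022,NPK,17.39,0.53
NH4,2022,CM,18.29,0.19
NH4,2022,PM,19.66,0.67
NH4,2022,SM,18.96,0.65
NH4,2023,NPK,17.69,0.17
NH4,2023,CM,18.76,0.14
NH4,2023,PM,20.33,0.54
NH4,2023,SM,19.47,1.18
NO3,2022,NPK,8.95,0.10
NO3,2022,CM,9.89,0.27
NO3,2022,PM,10.92,0.37
NO3,2022,SM,10.35,0.70
NO3,2023,NPK,10.15,0.29
NO3,2023,CM,11.37,0.12
NO3,2023,PM,12.87,0.27
NO3,2023,SM,11.93,0.96
AP,2022,NPK,31.12,4.10
AP,2022,CM,38.66,1.80
AP,2022,PM,48.29,3.29
AP,2022,SM,40.89,1.35
AP,2023,NPK,35.88,4.57
AP,2023,CM,44.91,1.96
AP,2023,PM,56.77,3.02
AP,2023,SM,47.98,2.50
AK,2022,NPK,102.17,1.80
AK,2022,CM,142.59,3.52
AK,2022,PM,95.65,7.50
AK,2022,SM,129.70,3.01
AK,2023,NPK,101.16,7.41
AK,2023,CM,129.80,2.70
AK,2023,PM,87.41,1.16
AK,2023,SM,121.56,5.73
CAT,2022,NPK,0.84,0.02
CAT,2022,CM,1.03,0.04
CAT,2022,PM,0.92,0.04
CAT,2022,SM,1.03,0.06
CAT,2023,NPK,0.91,0.02
CAT,2023,CM,1.25,0.02
CAT,2023,PM,1.03,0.06
CAT,2023,SM,1.16,0.05
INV,2022,NPK,17.87,0.61
INV,2022,CM,19.59,0.79
INV,2022,PM,23.38,2.38
INV,2022,SM,22.21,2.28
INV,2023,NPK,18.26,1.39
INV,2023,CM,20.06,0.14
INV,2023,PM,25.12,1.31
INV,2023,SM,23.05,1.03
NAG,2022,NPK,6.02,0.14
NAG,2022,CM,6.69,0.32
NAG,2022,PM,7.03,0.13
NAG,2022,SM,7.42,0.32
NAG,2023,NPK,6.46,0.37
NAG,2023,CM,7.42,0.19
NAG,2023,PM,7.82,0.35
NAG,2023,SM,8.29,0.19
URE,2022,NPK,0.39,0.01
URE,2022,CM,0.54,0.06
URE,2022,PM,0.63,0.02
URE,2022,SM,0.50,0.01
URE,2023,NPK,0.48,0.02
URE,2023,CM,0.69,0.07
URE,2023,PM,0.90,0.07
URE,2023,SM,0.62,0.01
ALP,2022,NPK,0.09,0.01
ALP,2022,CM,0.15,0.01
ALP,2022,PM,0.12,0.02
ALP,2022,SM,0.11,0.01
ALP,2023,NPK,0.09,0.01
ALP,2023,CM,0.16,0.01
ALP,2023,PM,0.14,0.01
ALP,2023,SM,0.12,0.01
GLS,2022,NPK,25.47,3.53
GLS,2022,CM,31.80,1.64
GLS,2022,PM,37.64,3.82
GLS,2022,SM,28.44,0.72
GLS,2023,NPK,28.16,0.82
GLS,2023,CM,35.58,4.67
GLS,2023,PM,43.33,3.03
GLS,2023,SM,31.89,1.55
SQI,2022,NPK,0.36,0.08
SQI,2022,CM,1.44,0.30
SQI,2022,PM,1.58,0.04
SQI,2022,SM,1.64,0.03
SQI,2023,NPK,0.33,0.07
SQI,2023,CM,0.94,0.06
SQI,2023,PM,1.56,0.17
SQI,2023,SM,1.47,0.31
EMF,2022,NPK,-1.20,0.15
EMF,2022,CM,0.32,0.13
EMF,2022,PM,0.65,0.27
EMF,2022,SM,0.23,0.38
EMF,2023,NPK,-1.23,0.04
EMF,2023,CM,0.31,0.04
EMF,2023,PM,0.75,0.07
EMF,2023,SM,0.17,0.14
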