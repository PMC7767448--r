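channel	x	y	z
FP1	-18.47	59.33	3.07
FPZ	0	63.15	3.07
FP2	18.47	59.33	3.07
AF3	-18.23	58.35	14.11
AF4	18.23	58.35	14.11
F7	-48.35	30.94	3.07
F5	-38.3	43.65	14.11
F3	-25.35	50.05	24.78
F1	-11.77	49.13	34.66
FZ	0	41.25	43.35
F2	11.77	49.13	34.66
F4	25.35	50.05	24.78
F6	38.3	43.65	14.11
F8	48.35	30.94	3.07
FT7	-56.84	9.15	3.07
FC5	-46.68	29.35	19.52
FC3	-29.64	38.36	34.66
FC1	-11.94	33.05	47.13
FCZ	0	15.56	55.81
FC2	11.94	33.05	47.13
FC4	29.64	38.36	34.66
FC6	46.68	29.35	19.52
FT8	56.84	9.15	3.07
T7	-59.76	-15	3.07
C5	-55.83	-15	24.78
C3	-43.02	-15	43.35
C1	-23.37	-15	55.81
CZ	0	-15	60.2
C2	23.37	-15	55.81
C4	43.02	-15	43.35
C6	55.83	-15	24.78
T8	59.76	-15	3.07
TP7	-56.84	-39.15	3.07
CP5	-46.68	-59.35	19.52
CP3	-29.64	-68.36	34.66
CP1	-11.94	-63.05	47.13
CPZ	0	-45.56	55.81
CP2	11.94	-63.05	47.13
CP4	29.64	-68.36	34.66
CP6	46.68	-59.35	19.52
TP8	56.84	-39.15	3.07
P7	-48.35	-60.94	3.07
P5	-38.3	-73.65	14.11
P3	-25.35	-80.05	24.78
P1	-11.77	-79.13	34.66
PZ	0	-71.25	43.35
P2	11.77	-79.13	34.66
P4	25.35	-80.05	24.78
P6	38.3	-73.65	14.11
P8	48.35	-60.94	3.07
PO7	-35.13	-78.23	3.07
PO5	-24.2	-86.09	10.48
PO3	-12.1	-89.44	17.7
POZ	0	-88.01	24.78
PO4	12.1	-89.44	17.7
PO6	24.2	-86.09	10.48
PO8	35.13	-78.23	3.07
CB1	-16.75	-82.4	-18.33
O1	-18.47	-89.33	3.07
OZ	0	-93.15	3.07
O2	18.47	-89.33	3.07
CB2	16.75	-82.4	-18.33
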