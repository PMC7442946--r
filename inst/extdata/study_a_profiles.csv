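person_id,role,state,median,mean,sd
S1,participant,stress,0.35,0.41,0.27
S1,participant,fatigue,0.22,0.27,0.23
S1,participant,anxiety,0.30,0.37,0.27
S1,participant,wellbeing_computed,0.69,0.65,0.21
S1P1,peer,stress,0.70,0.62,0.27
S1P1,peer,fatigue,0.62,0.65,0.27
S1P1,peer,anxiety,0.70,0.57,0.29
S1P1,peer,wellbeing_computed,0.35,0.39,0.27
S2,participant,stress,0.17,0.28,0.29
S2,participant,fatigue,0.29,0.31,0.26
S2,participant,anxiety,0.19,0.31,0.33
S2,participant,wellbeing_computed,0.65,0.70,0.23
S2P1,peer,stress,0.72,0.62,0.30
S2P1,peer,fatigue,0.58,0.59,0.28
S2P1,peer,anxiety,0.37,0.34,0.23
S2P1,peer,wellbeing_computed,0.42,0.48,0.23
S3,participant,stress,0.61,0.51,0.30
S3,participant,fatigue,0.61,0.62,0.27
S3,participant,anxiety,0.37,0.39,0.24
S3,participant,wellbeing_computed,0.40,0.49,0.22
S3P1,peer,stress,0.52,0.49,0.27
S3P1,peer,fatigue,0.39,0.40,0.21
S3P1,peer,anxiety,0.48,0.50,0.27
S3P1,peer,wellbeing_computed,0.55,0.54,0.22
S4,participant,stress,0.18,0.26,0.26
S4,participant,fatigue,0.30,0.36,0.25
S4,participant,anxiety,0.35,0.43,0.32
S4,participant,wellbeing_computed,0.71,0.65,0.17
S4P1,peer,stress,0.65,0.60,0.30
S4P1,peer,fatigue,0.65,0.50,0.36
S4P1,peer,anxiety,0.79,0.63,0.33
S4P1,peer,wellbeing_computed,0.35,0.42,0.28
S5,participant,stress,0.11,0.23,0.28
S5,participant,fatigue,0.35,0.36,0.24
S5,participant,anxiety,0.00,0.10,0.23
S5,participant,wellbeing_computed,0.82,0.77,0.17
S5P1,peer,stress,0.64,0.58,0.32
S5P1,peer,fatigue,0.60,0.58,0.33
S5P1,peer,anxiety,0.12,0.19,0.28
S5P1,peer,wellbeing_computed,0.53,0.55,0.27
S6,participant,stress,0.37,0.44,0.28
S6,participant,fatigue,0.32,0.34,0.23
S6,participant,anxiety,0.40,0.43,0.22
S6,participant,wellbeing_computed,0.74,0.60,0.19
S6P1,peer,stress,0.49,0.49,0.23
S6P1,peer,fatigue,0.38,0.45,0.32
S6P1,peer,anxiety,0.46,0.43,0.24
S6P1,peer,wellbeing_computed,0.55,0.55,0.24
S7,participant,stress,0.13,0.17,0.20
S7,participant,fatigue,0.36,0.37,0.25
S7,participant,anxiety,0.12,0.15,0.20
S7,participant,wellbeing_computed,0.80,0.77,0.16
S7P1,peer,stress,0.55,0.58,0.22
S7P1,peer,fatigue,0.64,0.64,0.25
S7P1,peer,anxiety,0.68,0.60,0.23
S7P1,peer,wellbeing_computed,0.36,0.39,0.22
S7P2,peer,stress,0.31,0.34,0.22
S7P2,peer,fatigue,0.65,0.57,0.29
S7P2,peer,anxiety,0.34,0.39,0.29
S7P2,peer,wellbeing_computed,0.60,0.57,0.21
S8,participant,stress,0.08,0.18,0.25
S8,participant,fatigue,0.52,0.48,0.25
S8,participant,anxiety,0.07,0.14,0.22
S8,participant,wellbeing_computed,0.75,0.73,0.18
S8P1,peer,stress,0.70,0.68,0.19
S8P1,peer,fatigue,0.62,0.65,0.18
S8P1,peer,anxiety,0.67,0.57,0.23
S8P1,peer,wellbeing_computed,0.34,0.37,0.17
S8P2,peer,stress,0.43,0.41,0.25
S8P2,peer,fatigue,0.58,0.55,0.27
S8P2,peer,anxiety,0.47,0.47,0.25
S8P2,peer,wellbeing_computed,0.50,0.52,0.24
S9,participant,stress,0.00,0.16,0.26
S9,participant,fatigue,0.38,0.43,0.30
S9,participant,anxiety,0.26,0.27,0.29
S9,participant,wellbeing_computed,0.74,0.71,0.19
S9P1,peer,stress,0.42,0.43,0.31
S9P1,peer,fatigue,0.67,0.61,0.29
S9P1,peer,anxiety,0.68,0.56,0.25
S9P1,peer,wellbeing_computed,0.42,0.47,0.21
S9P2,peer,stress,0.50,0.55,0.27
S9P2,peer,fatigue,0.51,0.55,0.24
S9P2,peer,anxiety,0.45,0.58,0.34
S9P2,peer,wellbeing_computed,0.45,0.44,0.20
S10,participant,stress,0.58,0.61,0.32
S10,participant,fatigue,0.58,0.57,0.27
S10,participant,anxiety,0.68,0.61,0.28
S10,participant,wellbeing_computed,0.37,0.40,0.12
S10P1,peer,stress,0.36,0.38,0.28
S10P1,peer,fatigue,0.34,0.34,0.20
S10P1,peer,anxiety,0.34,0.44,0.28
S10P1,peer,wellbeing_computed,0.63,0.62,0.22
S10P2,peer,stress,0.19,0.39,0.43
S10P2,peer,fatigue,0.77,0.61,0.39
S10P2,peer,anxiety,0.42,0.48,0.46
S10P2,peer,wellbeing_computed,0.52,0.51,0.35
S11,participant,stress,0.48,0.52,0.23
S11,participant,fatigue,0.18,0.29,0.28
S11,participant,anxiety,0.41,0.42,0.22
S11,participant,wellbeing_computed,0.62,0.59,0.18
S11P1,peer,stress,0.49,0.49,0.23
S11P1,peer,fatigue,0.40,0.45,0.31
S11P1,peer,anxiety,0.52,0.51,0.25
S11P1,peer,wellbeing_computed,0.52,0.52,0.24
S11P2,peer,stress,0.48,0.42,0.34
S11P2,peer,fatigue,0.63,0.57,0.37
S11P2,peer,anxiety,0.50,0.50,0.24
S11P2,peer,wellbeing_computed,0.52,0.50,0.28
S12,participant,stress,0.36,0.46,0.29
S12,participant,fatigue,0.60,0.55,0.27
S12,participant,anxiety,0.07,0.19,0.28
S12,participant,wellbeing_computed,0.63,0.60,0.17
S12P1,peer,stress,0.67,0.56,0.33
S12P1,peer,fatigue,0.77,0.65,0.30
S12P1,peer,anxiety,0.57,0.49,0.31
S12P1,peer,wellbeing_computed,0.31,0.43,0.29
S12P2,peer,stress,0.10,0.24,0.32
S12P2,peer,fatigue,0.53,0.52,0.25
S12P2,peer,anxiety,0.00,0.19,0.29
S12P2,peer,wellbeing_computed,0.74,0.68,0.20
S13,participant,stress,0.38,0.40,0.30
S13,participant,fatigue,0.03,0.16,0.24
S13,participant,anxiety,0.30,0.31,0.25
S13,participant,wellbeing_computed,0.74,0.71,0.18
S13P1,peer,stress,0.43,0.47,0.36
S13P1,peer,fatigue,0.45,0.50,0.30
S13P1,peer,anxiety,0.41,0.38,0.33
S13P1,peer,wellbeing_computed,0.56,0.55,0.28
S13P2,peer,stress,0.51,0.55,0.27
S13P2,peer,fatigue,0.42,0.43,0.26
S13P2,peer,anxiety,0.61,0.62,0.22
S13P2,peer,wellbeing_computed,0.48,0.47,0.24
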