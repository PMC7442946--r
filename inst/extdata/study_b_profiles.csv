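person_id,role,state,median,mean,sd
S1,participant,stress,0.49,0.36,0.55
S1,participant,fatigue,0.58,0.37,0.60
S1,participant,anxiety,0.58,0.66,0.32
S1,participant,wellbeing,0.76,0.72,0.24
S1,participant,wellbeing_computed,0.39,0.52,0.30
S1P1,peer,stress,0.44,0.44,0.21
S1P1,peer,fatigue,0.50,0.47,0.23
S1P1,peer,anxiety,0.57,0.54,0.21
S1P1,peer,wellbeing,0.41,0.41,0.21
S1P1,peer,wellbeing_computed,0.51,0.49,0.21
S2,participant,stress,0.35,0.34,0.29
S2,participant,fatigue,0.42,0.44,0.27
S2,participant,anxiety,0.42,0.43,0.25
S2,participant,wellbeing,0.73,0.63,0.28
S2,participant,wellbeing_computed,0.66,0.63,0.28
S2P1,peer,stress,0.76,0.69,0.24
S2P1,peer,fatigue,0.59,0.57,0.20
S2P1,peer,anxiety,0.66,0.64,0.25
S2P1,peer,wellbeing,0.61,0.56,0.29
S2P1,peer,wellbeing_computed,0.26,0.35,0.22
S3,participant,stress,0.50,0.49,0.27
S3,participant,fatigue,0.60,0.58,0.27
S3,participant,anxiety,0.39,0.42,0.23
S3,participant,wellbeing,0.48,0.47,0.26
S3,participant,wellbeing_computed,0.37,0.43,0.28
S3P1,peer,stress,0.47,0.43,0.24
S3P1,peer,fatigue,0.58,0.53,0.32
S3P1,peer,anxiety,0.59,0.59,0.23
S3P1,peer,wellbeing,0.79,0.76,0.20
S3P1,peer,wellbeing_computed,0.39,0.43,0.29
S4,participant,stress,0.50,0.53,0.25
S4,participant,fatigue,0.56,0.59,0.25
S4,participant,anxiety,0.42,0.44,0.31
S4,participant,wellbeing,0.64,0.56,0.24
S4,participant,wellbeing_computed,0.56,0.52,0.25
S4P1,peer,stress,0.63,0.66,0.28
S4P1,peer,fatigue,0.75,0.67,0.25
S4P1,peer,anxiety,0.69,0.59,0.32
S4P1,peer,wellbeing,0.65,0.62,0.28
S4P1,peer,wellbeing_computed,0.31,0.39,0.30
S5,participant,stress,0.22,0.27,0.26
S5,participant,fatigue,0.15,0.24,0.27
S5,participant,anxiety,0.33,0.34,0.33
S5,participant,wellbeing,0.78,0.66,0.32
S5,participant,wellbeing_computed,0.67,0.67,0.27
S5P1,peer,stress,0.44,0.40,0.29
S5P1,peer,fatigue,0.31,0.41,0.32
S5P1,peer,anxiety,0.43,0.43,0.30
S5P1,peer,wellbeing,0.63,0.54,0.29
S5P1,peer,wellbeing_computed,0.59,0.56,0.29
S6,participant,stress,0.54,0.56,0.27
S6,participant,fatigue,0.53,0.54,0.24
S6,participant,anxiety,0.55,0.59,0.29
S6,participant,wellbeing,0.48,0.51,0.23
S6,participant,wellbeing_computed,0.45,0.39,0.26
S6P1,peer,stress,0.49,0.47,0.28
S6P1,peer,fatigue,0.51,0.50,0.29
S6P1,peer,anxiety,0.62,0.59,0.32
S6P1,peer,wellbeing,0.55,0.49,0.32
S6P1,peer,wellbeing_computed,0.47,0.48,0.29
S7,participant,stress,0.00,0.21,0.33
S7,participant,fatigue,0.54,0.56,0.20
S7,participant,anxiety,0.26,0.35,0.20
S7,participant,wellbeing,0.62,0.59,0.30
S7,participant,wellbeing_computed,0.81,0.66,0.27
S7P1,peer,stress,0.36,0.35,0.34
S7P1,peer,fatigue,0.55,0.56,0.28
S7P1,peer,anxiety,0.37,0.41,0.36
S7P1,peer,wellbeing,0.60,0.53,0.26
S7P1,peer,wellbeing_computed,0.66,0.59,0.30
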