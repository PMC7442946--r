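participant_id,peer_id,state,r_s,p_printed
S1,S1P1,stress,0.44,.02
S1,S1P1,fatigue,0.28,.15
S1,S1P1,anxiety,0.57,.002
S1,S1P1,wellbeing_computed,0.58,.001
S2,S2P1,stress,0.50,.003
S2,S2P1,fatigue,0.26,.15
S2,S2P1,anxiety,0.24,.17
S2,S2P1,wellbeing_computed,0.63,<.001
S3,S3P1,stress,-0.18,.36
S3,S3P1,fatigue,-0.16,.40
S3,S3P1,anxiety,-0.09,.64
S3,S3P1,wellbeing_computed,-0.15,.45
S4,S4P1,stress,0.06,.76
S4,S4P1,fatigue,-0.10,.62
S4,S4P1,anxiety,-0.09,.64
S4,S4P1,wellbeing_computed,0.09,.67
S5,S5P1,stress,-0.10,.62
S5,S5P1,fatigue,-0.23,.24
S5,S5P1,anxiety,-0.35,.07
S5,S5P1,wellbeing_computed,-0.19,.33
S6,S6P1,stress,-0.23,.23
S6,S6P1,fatigue,-0.11,.57
S6,S6P1,anxiety,0.27,.16
S6,S6P1,wellbeing_computed,-0.08,.66
S7,S7P1,stress,0.19,.33
S7,S7P1,fatigue,-0.01,.96
S7,S7P1,anxiety,-0.31,.11
S7,S7P1,wellbeing_computed,-0.13,.49
S7,S7P2,stress,-0.01,.96
S7,S7P2,fatigue,0.28,.14
S7,S7P2,anxiety,0.19,.32
S7,S7P2,wellbeing_computed,0.36,.05
S8,S8P1,stress,0.11,.57
S8,S8P1,fatigue,0.08,.68
S8,S8P1,anxiety,0.22,.25
S8,S8P1,wellbeing_computed,0.26,.18
S8,S8P2,stress,0.32,.10
S8,S8P2,fatigue,0.59,<.001
S8,S8P2,anxiety,0.33,.08
S8,S8P2,wellbeing_computed,0.63,<.001
S9,S9P1,stress,-0.25,.16
S9,S9P1,fatigue,-0.05,.80
S9,S9P1,anxiety,-0.28,.10
S9,S9P1,wellbeing_computed,-0.37,.03
S9,S9P2,stress,0.02,.91
S9,S9P2,fatigue,0.29,.10
S9,S9P2,anxiety,-0.09,.60
S9,S9P2,wellbeing_computed,-0.16,.38
S10,S10P1,stress,0.29,.13
S10,S10P1,fatigue,-0.18,.35
S10,S10P1,anxiety,0.04,.84
S10,S10P1,wellbeing_computed,0.35,.06
S10,S10P2,stress,0.14,.48
S10,S10P2,fatigue,0.05,.80
S10,S10P2,anxiety,-0.15,.45
S10,S10P2,wellbeing_computed,-0.14,.46
S11,S11P1,stress,0.39,.03
S11,S11P1,fatigue,0.39,.03
S11,S11P1,anxiety,-0.06,.75
S11,S11P1,wellbeing_computed,0.28,.13
S11,S11P2,stress,0.07,.70
S11,S11P2,fatigue,0.03,.89
S11,S11P2,anxiety,-0.06,.75
S11,S11P2,wellbeing_computed,0.15,.42
S12,S12P1,stress,0.32,.10
S12,S12P1,fatigue,0.27,.16
S12,S12P1,anxiety,0.21,.28
S12,S12P1,wellbeing_computed,0.56,.002
S12,S12P2,stress,0.07,.73
S12,S12P2,fatigue,-0.24,.22
S12,S12P2,anxiety,-0.02,.94
S12,S12P2,wellbeing_computed,0.07,.71
S13,S13P1,stress,0.41,.02
S13,S13P1,fatigue,-0.19,.30
S13,S13P1,anxiety,0.41,.02
S13,S13P1,wellbeing_computed,0.27,.14
S13,S13P2,stress,0.36,.05
S13,S13P2,fatigue,-0.34,.06
S13,S13P2,anxiety,0.43,.02
S13,S13P2,wellbeing_computed,0.27,.15
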