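participant_id,peer_id,state,r_s,p_printed
S1,S1P1,stress,-0.39,.02
S1,S1P1,fatigue,-0.36,.03
S1,S1P1,anxiety,-0.33,.05
S1,S1P1,wellbeing,0.18,.30
S1,S1P1,wellbeing_computed,-0.30,.08
S2,S2P1,stress,-0.31,.10
S2,S2P1,fatigue,0.33,.08
S2,S2P1,anxiety,0.26,.18
S2,S2P1,wellbeing,0.40,.03
S2,S2P1,wellbeing_computed,0.13,.51
S3,S3P1,stress,0.37,.04
S3,S3P1,fatigue,0.44,.01
S3,S3P1,anxiety,0.04,.84
S3,S3P1,wellbeing,-0.08,.68
S3,S3P1,wellbeing_computed,0.44,.01
S4,S4P1,stress,0.24,.21
S4,S4P1,fatigue,0.16,.42
S4,S4P1,anxiety,0.10,.60
S4,S4P1,wellbeing,-0.17,.38
S4,S4P1,wellbeing_computed,0.37,.048
S5,S5P1,stress,0.04,.84
S5,S5P1,fatigue,0.03,.88
S5,S5P1,anxiety,0.06,.76
S5,S5P1,wellbeing,0.28,.13
S5,S5P1,wellbeing_computed,-0.01,.95
S6,S6P1,stress,0.44,.07
S6,S6P1,fatigue,-0.06,.81
S6,S6P1,anxiety,0.24,.34
S6,S6P1,wellbeing,0.83,<.001
S6,S6P1,wellbeing_computed,0.26,.30
S7,S7P1,stress,0.41,.03
S7,S7P1,fatigue,0.20,.29
S7,S7P1,anxiety,-0.25,.19
S7,S7P1,wellbeing,0.58,<.001
S7,S7P1,wellbeing_computed,-0.58,.001
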