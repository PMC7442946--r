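peer_id,state,p_printed
S1P1,stress,.003
S1P1,fatigue,.03
S1P1,anxiety,.01
S1P1,wellbeing,.07
S1P1,wellbeing_computed,.42
S2P1,stress,.001
S2P1,fatigue,.02
S2P1,anxiety,.002
S2P1,wellbeing,.30
S2P1,wellbeing_computed,<.001
S3P1,stress,.21
S3P1,fatigue,.18
S3P1,anxiety,.01
S3P1,wellbeing,<.001
S3P1,wellbeing_computed,.50
S4P1,stress,.01
S4P1,fatigue,.29
S4P1,anxiety,.07
S4P1,wellbeing,.64
S4P1,wellbeing_computed,.05
S5P1,stress,.02
S5P1,fatigue,.02
S5P1,anxiety,.35
S5P1,wellbeing,.03
S5P1,wellbeing_computed,.13
S6P1,stress,.06
S6P1,fatigue,.50
S6P1,anxiety,.56
S6P1,wellbeing,.45
S6P1,wellbeing_computed,.06
S7P1,stress,<.001
S7P1,fatigue,.03
S7P1,anxiety,.01
S7P1,wellbeing,.07
S7P1,wellbeing_computed,.01
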