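peer_id,state,p_printed
S1P1,stress,.001
S1P1,fatigue,<.001
S1P1,anxiety,<.001
S1P1,wellbeing_computed,.34
S2P1,stress,<.001
S2P1,fatigue,<.001
S2P1,anxiety,.58
S2P1,wellbeing_computed,.002
S3P1,stress,.74
S3P1,fatigue,.004
S3P1,anxiety,.21
S3P1,wellbeing_computed,<.001
S4P1,stress,<.001
S4P1,fatigue,.19
S4P1,anxiety,.07
S4P1,wellbeing_computed,.002
S5P1,stress,<.001
S5P1,fatigue,.03
S5P1,anxiety,.09
S5P1,wellbeing_computed,<.001
S6P1,stress,.96
S6P1,fatigue,.63
S6P1,anxiety,.09
S6P1,wellbeing_computed,.61
S7P2,stress,.003
S7P2,fatigue,.002
S7P2,anxiety,.001
S7P2,wellbeing_computed,.18
S8P2,stress,<.001
S8P2,fatigue,.13
S8P2,anxiety,<.001
S8P2,wellbeing_computed,<.001
S9P1,stress,<.001
S9P1,fatigue,.02
S9P1,anxiety,<.001
S9P1,wellbeing_computed,.23
S9P2,stress,<.001
S9P2,fatigue,.05
S9P2,anxiety,.001
S9P2,wellbeing_computed,<.001
S10P1,stress,<.001
S10P1,fatigue,<.001
S10P1,anxiety,.02
S10P1,wellbeing_computed,.28
S10P2,stress,.36
S10P2,fatigue,.01
S10P2,anxiety,.29
S10P2,wellbeing_computed,.72
S11P1,stress,.37
S11P1,fatigue,.003
S11P1,anxiety,.40
S11P1,wellbeing_computed,<.001
S11P2,stress,.77
S11P2,fatigue,<.001
S11P2,anxiety,.10
S11P2,wellbeing_computed,<.001
S12P1,stress,.22
S12P1,fatigue,.01
S12P1,anxiety,<.001
S12P1,wellbeing_computed,<.001
S12P2,stress,.03
S12P2,fatigue,.82
S12P2,anxiety,.94
S12P2,wellbeing_computed,<.001
S13P1,stress,.06
S13P1,fatigue,<.001
S13P1,anxiety,.12
S13P1,wellbeing_computed,.002
S13P2,stress,.13
S13P2,fatigue,.43
S13P2,anxiety,.80
S13P2,wellbeing_computed,.19
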