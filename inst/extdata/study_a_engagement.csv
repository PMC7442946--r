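person_id,role,days,triggered,response_rate,relationship
S1,participant,27,220,61.8,
S1P1,peer,27,127,87.4,parent
S2,participant,31,147,68.0,
S2P1,peer,31,100,61.0,parent
S3,participant,29,243,97.9,
S3P1,peer,29,220,35.5,friend
S4,participant,28,211,36.5,
S4P1,peer,27,165,15.2,parent
S5,participant,29,265,47.9,
S5P1,peer,27,252,23.0,sibling
S6,participant,29,243,97.5,
S6P1,peer,22,183,61.7,boyfriend
S7,participant,29,245,70.6,
S7P1,peer,20,122,30.3,friend
S7P2,peer,29,199,50.8,parent
S8,participant,28,250,94.0,
S8P1,peer,26,214,32.2,friend
S8P2,peer,28,213,61.5,boyfriend
S9,participant,34,225,44.9,
S9P1,peer,33,130,36.9,friend
S9P2,peer,33,133,45.9,sibling
S10,participant,29,267,31.1,
S10P1,peer,30,102,41.2,girlfriend
S10P2,peer,16,152,4.6,friend
S11,participant,29,250,82.0,
S11P1,peer,22,153,86.3,friend
S11P2,peer,17,100,50.0,sibling
S12,participant,28,252,77.4,
S12P1,peer,26,198,13.1,sibling
S12P2,peer,26,206,50.0,friend
S13,participant,30,268,35.1,
S13P1,peer,15,130,9.2,parent
S13P2,peer,14,79,79.7,friend
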