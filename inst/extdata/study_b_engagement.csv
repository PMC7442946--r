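person_id,role,days,triggered,response_rate,relationship
S1,participant,31,93,69.9,
S1P1,peer,31,93,172.0,friend
S2,participant,28,84,78.6,
S2P1,peer,28,84,77.4,friend
S3,participant,28,84,108.3,
S3P1,peer,28,84,60.7,spouse
S4,participant,28,84,69.0,
S4P1,peer,28,84,59.5,spouse
S5,participant,28,84,50.0,
S5P1,peer,27,81,28.4,spouse
S6,participant,17,51,96.1,
S6P1,peer,16,48,102.1,friend
S7,participant,27,81,91.4,
S7P1,peer,28,84,40.5,friend
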