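category	kos
peptidases	K76001,K76002,K76003,K76004,K76005,K76006,K76007,K76008,K76009,K76010,K76011,K76012
amino_acid_metabolism	K76101,K76102,K76103,K76104,K76105,K76106,K76107,K76108,K76109,K76110,K76111,K76112,K76113,K76114,K76115
amino_acid_transporters	K76201,K76202,K76203,K76204,K76205,K76206,K76207,K76208,K76209,K76210
phosphofructokinase	K00850
acetate	K00925,K00625,K01895,K13788
propionate	K01895,K01026
butyrate	K01034,K01035,K01896,K00929,K00634
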