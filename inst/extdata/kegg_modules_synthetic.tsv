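module_id	description	kos
M00377	Reductive acetyl-CoA pathway (Wood-Ljungdahl pathway)	K75001,K75002,K75003,K75004,K75005,K75006,K75007,K75008,K75009,K75010
M00422	Acetyl-CoA pathway, CO2 => acetyl-CoA	K75011,K75012,K75013,K75014,K75015
M00196	Multiple sugar transport system	K75016,K75017,K75018,K75019
M00018	Threonine biosynthesis, aspartate => homoserine => threonine	K75021,K75022,K75023,K75024,K75025,K75026,K75027,K75028,K75029,K75030
M00299	Spermidine/putrescine transport system	K75031,K75032,K75033,K75034
M00236	Putative polar amino acid transport system	K75035,K75036,K75037
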