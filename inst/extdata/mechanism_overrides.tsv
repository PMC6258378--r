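case_id	mechanism	reason
P2109_188	chromothripsis	expert call: large alt-NHEJ insertion scars interpreted as replicative-error joining of shattered fragments, not chromoanasynthesis
P2046_133	ambiguous	expert call: a 27-bp non-templated insertion outweighs the NHEJ-dominated junction profile
P1426_301	ambiguous	expert call: large non-templated insertions (8-52 bp) with short microhomology not fully consistent with FoSTeS/MMBIR
P72	chromothripsis	no junction resolved at nucleotide level; call rests on the deletions-only copy-number profile
P74	chromoanasynthesis	no junction resolved at nucleotide level; call rests on the duplications-only copy-number profile
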