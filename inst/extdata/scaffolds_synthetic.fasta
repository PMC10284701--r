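>tS_scaffold synthetic serine-tRNA scaffold, reconstructed cloverleaf (natural anticodon UGA)
GUAGUCGUGGCCGAGUGGUUAAGGCGAUGGCCUUGAAAGCCAUUGGGGUUUCCCCGCGCGGGUUCGAAUCCCGCCGACUACG
>tR_scaffold synthetic arginine-tRNA scaffold (natural anticodon UCU)
GGGCCAGUAGCUCAGUUGGAAGAGCCUGGCUUCUAACCAGGAGGUCGCGGGUUCGAAUCCCGCCUGGCCCG
>tG_scaffold synthetic glycine-tRNA scaffold (natural anticodon UCC)
GCGGGAAUAGCUCAGUUGGUAGAGCGGUUCUUCCAAAACCGGGUCAGCGGGUUCGAAUCCCGCUUCCCGCA
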