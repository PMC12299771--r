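smiles,label
"C(Cl)CCC(c1ccccc1)CCC(Cl)C",Plastic
"CC(c1ccccc1)CCC(CC)CCCC(C)C",Plastic
"OC(=O)[C@]([H])(CCSC)NC(=O)[C@]([H])(CC(C)C)NC(=O)[C@]([H])(CC(C)C)N",Peptide
"OC(=O)[C@]([H])(CO)NC(=O)[C@]([H])(C1CCCN1)NC(=O)[C@]([H])([H])N",Peptide
"O[C@]([C@]([H])(CO)O[C@](O)([H])[C@]([H])1O)([H])[C@]1([H])O[C@]([C@]([H])(CO)O[C@](O)([H])[C@]([H])1O)([H])[C@]1([H])O[C@@]([C@]([H])(CO)O[C@](O)([H])[C@@]([H])1O)([H])[C@]1([H])O",Oligosaccharide
"O[C@]([C@@]([H])(CO)O[C@@](O)([H])[C@]([H])1O)([H])[C@@]1([H])N[C@]([C@]([H])(CO)O[C@](O)([H])[C@]([H])1O)([H])[C@]1([H])O[C@]([C@]([H])(CO)O[C@](O)([H])[C@]([H])1O)([H])[C@@]1([H])O[C@]([C@]([H])(CO)O[C@](O)([H])[C@]([H])1O)([H])[C@@]1([H])O",Oligosaccharide
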