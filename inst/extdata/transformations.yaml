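# Phase I/II hepatic transformation library: named elemental-composition
# deltas in the signed table dialect. Phase I are functionalization
# reactions; phase II are conjugations. Deiodination and the other
# dehalogenations only ever apply to parents carrying the halogen, which the
# enumerator enforces by pruning products with negative element counts.
- {name: "Oxidation",                       phase: phase1, delta: "+(O)"}
- {name: "Reduction",                       phase: phase1, delta: "+(H2)"}
- {name: "Desaturation",                    phase: phase1, delta: "-(H2)"}
- {name: "Hydration",                       phase: phase1, delta: "+(H2 O)"}
- {name: "Dehydration",                     phase: phase1, delta: "-(H2 O)"}
- {name: "Methylation",                     phase: phase1, delta: "+(C H2)"}
- {name: "Demethylation",                   phase: phase1, delta: "-(C H2)"}
- {name: "Deethylation",                    phase: phase1, delta: "-(C2 H4)"}
- {name: "Acetylation",                     phase: phase1, delta: "+(C2 H2 O)"}
- {name: "Decarboxylation",                 phase: phase1, delta: "-(C O2)"}
- {name: "Ring Open",                       phase: phase1, delta: "+(H2 O)"}
- {name: "Hydrolysis",                      phase: phase1, delta: "+(H2 O)"}
- {name: "Nitro Reduction",                 phase: phase1, delta: "-(O2) +(H2)"}
- {name: "Deiodination",                    phase: phase1, delta: "-(I) +(H)"}
- {name: "Reductive Dechlorination",        phase: phase1, delta: "-(Cl) +(H)"}
- {name: "Oxidative Dechlorination",        phase: phase1, delta: "-(Cl) +(H O)"}
- {name: "Oxidative Debromination",         phase: phase1, delta: "-(Br) +(H O)"}
- {name: "Oxidative Deamination to Alcohol", phase: phase1, delta: "-(H N) +(O)"}
- {name: "Oxidative Deamination to Ketone", phase: phase1, delta: "-(H3 N) +(O)"}
- {name: "Glucuronide Conjugation",         phase: phase2, delta: "+(C6 H8 O6)"}
- {name: "Sulfation",                       phase: phase2, delta: "+(O3 S)"}
- {name: "GSH Conjugation",                 phase: phase2, delta: "+(C10 H15 N3 O6 S)"}
- {name: "Glucoside Conjugation",           phase: phase2, delta: "+(C6 H10 O5)"}
- {name: "Taurine Conjugation",             phase: phase2, delta: "+(C2 H5 N O2 S)"}
- {name: "Glutamine Conjugation",           phase: phase2, delta: "+(C5 H8 N2 O2)"}
- {name: "Arginine Conjugation",            phase: phase2, delta: "+(C6 H12 N4 O)"}
- {name: "Palmitoyl Conjugation",           phase: phase2, delta: "+(C16 H30 O)"}
- {name: "Stearyl Conjugation",             phase: phase2, delta: "+(C18 H34 O)"}
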