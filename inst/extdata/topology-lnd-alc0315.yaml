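molecules:
  ALCP:
    species_class: IL_PROTONATED
    head_terminal_bead: OH
    rdf_bead: NC3
  ALCD:
    species_class: IL_DEPROTONATED
    head_terminal_bead: OH
    rdf_bead: NC3
  MC3P:
    species_class: IL_PROTONATED
    head_terminal_bead: NC3
    rdf_bead: NC3
  MC3D:
    species_class: IL_DEPROTONATED
    head_terminal_bead: NC3
    rdf_bead: NC3
  DSPC:
    species_class: PHOSPHOLIPID
    head_terminal_bead: NC3
    origin: LND
  POPC:
    species_class: PHOSPHOLIPID
  DOPE:
    species_class: PHOSPHOLIPID
  POPS:
    species_class: ANIONIC_LIPID
  CHOL:
    species_class: STEROL
  W:
    species_class: WATER
  NA+:
    species_class: ION
  CL-:
    species_class: ION
segments:
- molecule: ALCP
  chain: sn1
  label: GL1-T1
  bead_a: GL1
  bead_b: T1
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn1
  label: T1-T2
  bead_a: T1
  bead_b: T2
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn1
  label: T2-T3
  bead_a: T2
  bead_b: T3
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn1
  label: T3-T4
  bead_a: T3
  bead_b: T4
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn1
  label: T4-T5
  bead_a: T4
  bead_b: T5
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn1
  label: T1-T3
  bead_a: T1
  bead_b: T3
  kind: NONCONSECUTIVE
- molecule: ALCP
  chain: sn1
  label: T1-T5
  bead_a: T1
  bead_b: T5
  kind: NONCONSECUTIVE
- molecule: ALCP
  chain: sn2
  label: GL2-T6
  bead_a: GL2
  bead_b: T6
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn2
  label: T6-T7
  bead_a: T6
  bead_b: T7
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn2
  label: T7-T8
  bead_a: T7
  bead_b: T8
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn2
  label: T8-T9
  bead_a: T8
  bead_b: T9
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn2
  label: T9-T10
  bead_a: T9
  bead_b: T10
  kind: CONSECUTIVE_BOND
- molecule: ALCP
  chain: sn2
  label: T6-T8
  bead_a: T6
  bead_b: T8
  kind: NONCONSECUTIVE
- molecule: ALCP
  chain: sn2
  label: T6-T10
  bead_a: T6
  bead_b: T10
  kind: NONCONSECUTIVE
- molecule: ALCD
  chain: sn1
  label: GL1-T1
  bead_a: GL1
  bead_b: T1
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn1
  label: T1-T2
  bead_a: T1
  bead_b: T2
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn1
  label: T2-T3
  bead_a: T2
  bead_b: T3
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn1
  label: T3-T4
  bead_a: T3
  bead_b: T4
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn1
  label: T4-T5
  bead_a: T4
  bead_b: T5
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn1
  label: T1-T3
  bead_a: T1
  bead_b: T3
  kind: NONCONSECUTIVE
- molecule: ALCD
  chain: sn1
  label: T1-T5
  bead_a: T1
  bead_b: T5
  kind: NONCONSECUTIVE
- molecule: ALCD
  chain: sn2
  label: GL2-T6
  bead_a: GL2
  bead_b: T6
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn2
  label: T6-T7
  bead_a: T6
  bead_b: T7
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn2
  label: T7-T8
  bead_a: T7
  bead_b: T8
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn2
  label: T8-T9
  bead_a: T8
  bead_b: T9
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn2
  label: T9-T10
  bead_a: T9
  bead_b: T10
  kind: CONSECUTIVE_BOND
- molecule: ALCD
  chain: sn2
  label: T6-T8
  bead_a: T6
  bead_b: T8
  kind: NONCONSECUTIVE
- molecule: ALCD
  chain: sn2
  label: T6-T10
  bead_a: T6
  bead_b: T10
  kind: NONCONSECUTIVE
- molecule: MC3P
  chain: sn1
  label: CA1-CA2
  bead_a: CA1
  bead_b: CA2
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn1
  label: CA2-CA3
  bead_a: CA2
  bead_b: CA3
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn1
  label: CA3-CA4
  bead_a: CA3
  bead_b: CA4
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn1
  label: CA4-CA5
  bead_a: CA4
  bead_b: CA5
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn1
  label: CA1-CA3
  bead_a: CA1
  bead_b: CA3
  kind: NONCONSECUTIVE
- molecule: MC3P
  chain: sn1
  label: CA1-CA5
  bead_a: CA1
  bead_b: CA5
  kind: NONCONSECUTIVE
- molecule: MC3P
  chain: sn2
  label: CB1-CB2
  bead_a: CB1
  bead_b: CB2
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn2
  label: CB2-CB3
  bead_a: CB2
  bead_b: CB3
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn2
  label: CB3-CB4
  bead_a: CB3
  bead_b: CB4
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn2
  label: CB4-CB5
  bead_a: CB4
  bead_b: CB5
  kind: CONSECUTIVE_BOND
- molecule: MC3P
  chain: sn2
  label: CB1-CB3
  bead_a: CB1
  bead_b: CB3
  kind: NONCONSECUTIVE
- molecule: MC3P
  chain: sn2
  label: CB1-CB5
  bead_a: CB1
  bead_b: CB5
  kind: NONCONSECUTIVE
- molecule: MC3D
  chain: sn1
  label: CA1-CA2
  bead_a: CA1
  bead_b: CA2
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn1
  label: CA2-CA3
  bead_a: CA2
  bead_b: CA3
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn1
  label: CA3-CA4
  bead_a: CA3
  bead_b: CA4
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn1
  label: CA4-CA5
  bead_a: CA4
  bead_b: CA5
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn1
  label: CA1-CA3
  bead_a: CA1
  bead_b: CA3
  kind: NONCONSECUTIVE
- molecule: MC3D
  chain: sn1
  label: CA1-CA5
  bead_a: CA1
  bead_b: CA5
  kind: NONCONSECUTIVE
- molecule: MC3D
  chain: sn2
  label: CB1-CB2
  bead_a: CB1
  bead_b: CB2
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn2
  label: CB2-CB3
  bead_a: CB2
  bead_b: CB3
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn2
  label: CB3-CB4
  bead_a: CB3
  bead_b: CB4
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn2
  label: CB4-CB5
  bead_a: CB4
  bead_b: CB5
  kind: CONSECUTIVE_BOND
- molecule: MC3D
  chain: sn2
  label: CB1-CB3
  bead_a: CB1
  bead_b: CB3
  kind: NONCONSECUTIVE
- molecule: MC3D
  chain: sn2
  label: CB1-CB5
  bead_a: CB1
  bead_b: CB5
  kind: NONCONSECUTIVE
- molecule: POPC
  chain: sn1
  label: GL1-C1A
  bead_a: GL1
  bead_b: C1A
  kind: CONSECUTIVE_BOND
- molecule: POPC
  chain: sn1
  label: C1A-C2A
  bead_a: C1A
  bead_b: C2A
  kind: CONSECUTIVE_BOND
- molecule: POPC
  chain: sn1
  label: GL1-C2A
  bead_a: GL1
  bead_b: C2A
  kind: NONCONSECUTIVE
- molecule: POPC
  chain: sn2
  label: GL2-C1B
  bead_a: GL2
  bead_b: C1B
  kind: CONSECUTIVE_BOND
- molecule: POPC
  chain: sn2
  label: C1B-C2B
  bead_a: C1B
  bead_b: C2B
  kind: CONSECUTIVE_BOND
- molecule: POPC
  chain: sn2
  label: GL2-C2B
  bead_a: GL2
  bead_b: C2B
  kind: NONCONSECUTIVE
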