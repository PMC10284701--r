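# Aminoacyl-tRNA-synthetase identity elements per tRNA family.
# Serine: discriminator base G73 and the long variable arm (seryl-tRNA
# synthetase reads the V-arm, not the anticodon). Arginine: G73, A20 and
# the anticodon bases C35 plus U or G at 36. Glycine: A73 and the
# acceptor-stem pair C2-G71.
families:
  - family: Ser
    constraints:
      - kind: position-nt
        pos: "73"
        nt: G
      - kind: segment-preserved
        segment: V-region
  - family: Arg
    constraints:
      - kind: position-nt
        pos: "73"
        nt: G
      - kind: position-nt
        pos: "20"
        nt: A
      - kind: position-nt
        pos: "35"
        nt: C
      - kind: position-nt-choice
        pos: "36"
        nts: [U, G]
  - family: Gly
    constraints:
      - kind: position-nt
        pos: "73"
        nt: A
      - kind: pair
        pos5: "2"
        pos3: "71"
        nt5: C
        nt3: G
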