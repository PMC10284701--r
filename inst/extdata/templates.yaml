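# Edit templates for suppressor-tRNA variants.
# A-templates edit the anticodon stem; T-templates edit the T-stem base
# pairs that tune eEF1A binding. The A2 graft halves are the
# selenocysteine-tRNA anticodon stem as carried by the tSA2T5 design.
templates:
  - id: A1
    description: weaken-and-tune anticodon stem, U-A pair at positions 31/39
    edits:
      - kind: set-pair
        pos5: "31"
        pos3: "39"
        nt5: U
        nt3: A
  - id: A2
    description: anticodon stem grafted from tRNA-Sec (both halves)
    edits:
      - kind: graft-segment
        segment: anticodon-stem5
        replacement: GCAGG
      - kind: graft-segment
        segment: anticodon-stem3
        replacement: CCUGU
  - id: T2
    description: destabilize eEF1A binding via pair 51/63
    edits:
      - kind: set-pair
        pos5: "51"
        pos3: "63"
        nt5: U
        nt3: A
  - id: T5
    description: moderately destabilize eEF1A binding via pair 49/65
    edits:
      - kind: set-pair
        pos5: "49"
        pos3: "65"
        nt5: A
        nt3: U
  - id: T6
    description: stabilize eEF1A binding via pair 49/65
    edits:
      - kind: set-pair
        pos5: "49"
        pos3: "65"
        nt5: C
        nt3: G
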