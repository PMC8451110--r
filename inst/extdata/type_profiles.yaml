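# Default nsLTP type profiles: allowed inter-cysteine gap ranges (g1..g5,
# residues strictly between the motif cysteines), expected intron counts and
# GPI expectation per Edstam-style type. These ranges are editable
# configuration derived from the plant nsLTP classification literature, not
# values asserted by any single study; load your own file to override.
types:
  - type: "1"
    g1: [8, 10]
    g2: [12, 16]
    g3: [17, 21]
    g4: [20, 24]
    g5: [10, 14]
    introns: [1]
    gpi: false
  - type: "2"
    g1: [6, 8]
    g2: [11, 14]
    g3: [7, 11]
    g4: [20, 24]
    g5: [5, 8]
    introns: [0]
    gpi: false
  - type: "C"
    g1: [3, 5]
    g2: [11, 14]
    g3: [12, 16]
    g4: [14, 18]
    g5: [5, 8]
    introns: [1]
    gpi: false
  - type: "D"
    g1: [8, 10]
    g2: [12, 16]
    g3: [12, 16]
    g4: [25, 29]
    g5: [10, 14]
    introns: [0, 1]
    gpi: false
  - type: "E"
    g1: [11, 13]
    g2: [12, 16]
    g3: [27, 31]
    g4: [20, 24]
    g5: [5, 8]
    introns: [1]
    gpi: false
  - type: "F"
    g1: [6, 8]
    g2: [17, 20]
    g3: [32, 36]
    g4: [20, 24]
    g5: [10, 14]
    introns: [1]
    gpi: false
  - type: "G"
    g1: [8, 10]
    g2: [12, 16]
    g3: [22, 26]
    g4: [20, 24]
    g5: [10, 14]
    introns: [2]
    gpi: true
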