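[
  {
    "id": 14,
    "note": "human HN muscle among the 13 major chimp-human HN-FL differences"
  },
  {
    "id": 16,
    "note": "human HN muscle (variant only in chimpanzees); major chimp-human difference"
  },
  {
    "id": 30,
    "note": "human HN muscle (variant only in chimpanzees); major chimp-human difference"
  },
  {
    "id": 66,
    "note": "single-bellied omohyoideus in bonobos: the one HN chimp-bonobo difference; two equal-cost placements (stem gain + bonobo loss, or independent gains in P. troglodytes and humans)"
  },
  {
    "id": 71,
    "note": "human FL muscle; major chimp-human difference"
  },
  {
    "id": 72,
    "note": "muscle present in common chimpanzees, absent in humans; major chimp-human difference"
  },
  {
    "id": 80,
    "note": "muscle present in common chimpanzees, absent in humans; major chimp-human difference"
  },
  {
    "id": 83,
    "note": "bonobo FL trait shared with humans; change reassigned to the P. troglodytes branch as a reversion to state 0"
  },
  {
    "id": 101,
    "note": "human FL muscle; major chimp-human difference"
  },
  {
    "id": 106,
    "note": "human FL muscle; major chimp-human difference"
  },
  {
    "id": 112,
    "note": "non-vestigial tendon in bonobos makes a stem gain with reversions in humans and bonobos equally parsimonious with independent acquisitions in common chimpanzees, gorillas and orangutans (3 steps)"
  },
  {
    "id": 120,
    "note": "one of the two Pan-clade synapomorphies: reversion to state 0 on the Pan stem"
  },
  {
    "id": 130,
    "note": "contrahentes to digits 4 and 5 encoded as two characters so the 13 major HN-FL differences are met"
  },
  {
    "id": 131,
    "note": "the other Pan-clade synapomorphy: reversion to state 0 on the Pan stem"
  },
  {
    "id": 135,
    "note": "human FL muscle; major chimp-human difference"
  },
  {
    "id": 140,
    "note": "dorsal interossei shared by bonobos and humans (one of the 2 major chimp-bonobo differences); change reassigned to the P. troglodytes branch as a reversion to state 0"
  },
  {
    "id": 150,
    "note": "synthetic: the 16 HN-FL chimp-human state differences are a printed tally, not an enumerated list; 15 are reconstructable (13 majors + chars 83 and 112), this placeholder supplies the 16th"
  },
  {
    "id": 167,
    "note": "usual absence in modern humans; major chimp-human HL difference"
  },
  {
    "id": 168,
    "note": "usual absence in modern humans; major chimp-human HL difference"
  },
  {
    "id": 169,
    "note": "usual absence in modern humans; major chimp-human HL difference"
  },
  {
    "id": 170,
    "note": "usual absence in modern humans; major chimp-human HL difference"
  },
  {
    "id": 171,
    "note": "usual absence in modern humans; major chimp-human HL difference"
  },
  {
    "id": 172,
    "note": "usual absence in modern humans; major chimp-human HL difference"
  },
  {
    "id": 173,
    "note": "human HL muscle; major chimp-human HL difference"
  },
  {
    "id": 174,
    "note": "attachment difference between common chimpanzees and humans"
  },
  {
    "id": 175,
    "note": "axis difference between common chimpanzees and humans"
  },
  {
    "id": 176,
    "note": "attachment difference between common chimpanzees and humans"
  },
  {
    "id": 177,
    "note": "attachment difference between common chimpanzees and humans"
  },
  {
    "id": 178,
    "note": "attachment difference between common chimpanzees and humans"
  },
  {
    "id": 179,
    "note": "bonobos retain a scansorius, missing in common chimpanzees and humans; one of the 2 major chimp-bonobo differences"
  },
  {
    "id": 180,
    "note": "bonobo HL attachment missing in common chimpanzees and humans"
  },
  {
    "id": 181,
    "note": "bonobo HL attachment missing in common chimpanzees and humans"
  }
]
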