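{
  "name": "igg_fc_glycosylation_pathway",
  "version": "1.0",
  "description": "Known human IgG Fc N-glycosylation pathway: biantennary complex-type structures and single-sugar-addition reactions catalysed by FUT8, B4GalT1, MGAT3 and ST6Gal1.",
  "panel": [
    {
      "name": "G0",
      "measured": true
    },
    {
      "name": "G1",
      "measured": true
    },
    {
      "name": "G2",
      "measured": true
    },
    {
      "name": "G0F",
      "measured": true
    },
    {
      "name": "G1F",
      "measured": true
    },
    {
      "name": "G2F",
      "measured": true
    },
    {
      "name": "G0N",
      "measured": true
    },
    {
      "name": "G1N",
      "measured": true
    },
    {
      "name": "G2N",
      "measured": true
    },
    {
      "name": "G0FN",
      "measured": true
    },
    {
      "name": "G1FN",
      "measured": true
    },
    {
      "name": "G2FN",
      "measured": true
    },
    {
      "name": "G1S1",
      "measured": true
    },
    {
      "name": "G2S1",
      "measured": true
    },
    {
      "name": "G1FS1",
      "measured": true
    },
    {
      "name": "G2FS1",
      "measured": true
    },
    {
      "name": "G1NS1",
      "measured": true
    },
    {
      "name": "G2NS1",
      "measured": true
    },
    {
      "name": "G1FNS1",
      "measured": true
    },
    {
      "name": "G2FNS1",
      "measured": true
    },
    {
      "name": "G2S2",
      "measured": false
    },
    {
      "name": "G2FS2",
      "measured": false
    }
  ],
  "reactions": [
    [
      "G0",
      "G0F",
      "FUT8"
    ],
    [
      "G0",
      "G0N",
      "MGAT3"
    ],
    [
      "G0",
      "G1",
      "B4GalT1"
    ],
    [
      "G1",
      "G2",
      "B4GalT1"
    ],
    [
      "G1",
      "G1S1",
      "ST6Gal1"
    ],
    [
      "G2",
      "G2S1",
      "ST6Gal1"
    ],
    [
      "G0F",
      "G0FN",
      "MGAT3"
    ],
    [
      "G0F",
      "G1F",
      "B4GalT1"
    ],
    [
      "G1F",
      "G2F",
      "B4GalT1"
    ],
    [
      "G1F",
      "G1FS1",
      "ST6Gal1"
    ],
    [
      "G2F",
      "G2FS1",
      "ST6Gal1"
    ],
    [
      "G0N",
      "G1N",
      "B4GalT1"
    ],
    [
      "G1N",
      "G2N",
      "B4GalT1"
    ],
    [
      "G1N",
      "G1NS1",
      "ST6Gal1"
    ],
    [
      "G2N",
      "G2NS1",
      "ST6Gal1"
    ],
    [
      "G0FN",
      "G1FN",
      "B4GalT1"
    ],
    [
      "G1FN",
      "G2FN",
      "B4GalT1"
    ],
    [
      "G1FN",
      "G1FNS1",
      "ST6Gal1"
    ],
    [
      "G2FN",
      "G2FNS1",
      "ST6Gal1"
    ],
    [
      "G2S1",
      "G2S2",
      "ST6Gal1"
    ],
    [
      "G2FS1",
      "G2FS2",
      "ST6Gal1"
    ]
  ],
  "rules": [
    {
      "id": "F1",
      "enzyme": "FUT8",
      "description": "fucosylation of galactosylated, non-bisected, asialo glycans",
      "predicate": {
        "gal_min": 1,
        "bis": false,
        "sia_max": 0
      }
    },
    {
      "id": "F2",
      "enzyme": "FUT8",
      "description": "fucosylation of bisected glycans",
      "predicate": {
        "bis": true
      }
    },
    {
      "id": "F3",
      "enzyme": "FUT8",
      "description": "fucosylation of sialylated, non-bisected glycans",
      "predicate": {
        "sia_min": 1,
        "bis": false
      }
    },
    {
      "id": "G1",
      "enzyme": "B4GalT1",
      "description": "galactosylation of sialylated glycans",
      "predicate": {
        "sia_min": 1
      }
    },
    {
      "id": "N1",
      "enzyme": "MGAT3",
      "description": "bisection of galactosylated, non-fucosylated glycans",
      "predicate": {
        "gal_min": 1,
        "fuc": false
      }
    },
    {
      "id": "N2",
      "enzyme": "MGAT3",
      "description": "bisection of galactosylated, fucosylated glycans",
      "predicate": {
        "gal_min": 1,
        "fuc": true
      }
    }
  ],
  "subclasses": {
    "IgG1": ["G0", "G1", "G2", "G0F", "G1F", "G2F", "G0N", "G1N", "G2N", "G0FN", "G1FN", "G2FN", "G1S1", "G2S1", "G1FS1", "G2FS1", "G1NS1", "G2NS1", "G1FNS1", "G2FNS1"],
    "IgG2": ["G0", "G1", "G2", "G0F", "G1F", "G2F", "G0N", "G1N", "G2N", "G0FN", "G1FN", "G2FN", "G1S1", "G2S1", "G1FS1", "G2FS1", "G1NS1", "G2NS1", "G1FNS1", "G2FNS1"],
    "IgG4": ["G0F", "G1F", "G2F", "G0FN", "G1FN", "G2FN", "G1FS1", "G2FS1", "G1FNS1", "G2FNS1"]
  }
}
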