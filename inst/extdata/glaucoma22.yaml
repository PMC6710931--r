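# Default 22-pathway glaucoma neuron-glia network.
# State order and reference-sensitivity layout follow the published table
# (note Mb listed before Ma, and the stress pool Cs in mid-table position).
metadata:
  name: glaucoma22
  description: >-
    22-pathway kinetic network of glaucoma pathogenesis: retinal ganglion
    cells, astroglia, microglia, Mueller glia and a lumped cell-stress pool.
  version: "1.0"
states:
  - {id: Rs, display_name: "surviving RGCs (Rσ)",        lineage: rgc,       mode: surviving,   initial_value: 1.0e4}
  - {id: Rd, display_name: "dead RGCs (Rδ)",             lineage: rgc,       mode: dead,        initial_value: 1.0e2}
  - {id: Aa, display_name: "quiescent astroglia (Aα)",   lineage: astroglia, mode: quiescent,   initial_value: 1.0e5}
  - {id: Ab, display_name: "proliferative astroglia (Aβ)", lineage: astroglia, mode: activated, initial_value: 1.0e3}
  - {id: Mb, display_name: "proinflammatory microglia (Mβ)", lineage: microglia, mode: activated, initial_value: 1.0e3}
  - {id: Ma, display_name: "antiinflammatory microglia (Mα)", lineage: microglia, mode: quiescent, initial_value: 1.0e5}
  - {id: Cs, display_name: "cell stress (Cσ)",           lineage: stress,    mode: stress_pool, initial_value: 1.0e3}
  - {id: Ga, display_name: "quiescent Mueller cells (Gα)", lineage: mueller,  mode: quiescent,   initial_value: 1.0e5}
  - {id: Gb, display_name: "reactive Mueller cells (Gβ)", lineage: mueller,   mode: activated,   initial_value: 1.0e3}
pathways:
  - {id: 1,  source: Aa, target: Rs, rate_name: k1,  rate_value: 1.0, annotation: homeostatic, efficacy_tier: very_high}
  - {id: 2,  source: Ab, target: Rd, rate_name: k2,  rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 3,  source: Mb, target: Rd, rate_name: k3,  rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 4,  source: Ma, target: Aa, rate_name: k4,  rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 5,  source: Mb, target: Ab, rate_name: k5,  rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 6,  source: Rs, target: Ma, rate_name: k6,  rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 7,  source: Aa, target: Ma, rate_name: k7,  rate_value: 1.0, annotation: homeostatic, efficacy_tier: very_high}
  - {id: 8,  source: Cs, target: Ma, rate_name: k8,  rate_value: 0.3, annotation: pathogenic,  efficacy_tier: moderate}
  - {id: 9,  source: Mb, target: Ma, rate_name: k9,  rate_value: 0.1, annotation: pathogenic,  efficacy_tier: low}
  - {id: 10, source: Rd, target: Mb, rate_name: k10, rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 11, source: Rs, target: Mb, rate_name: k11, rate_value: 0.3, annotation: pathogenic,  efficacy_tier: moderate}
  - {id: 12, source: Aa, target: Mb, rate_name: k12, rate_value: 1.0, annotation: pathogenic,  efficacy_tier: very_high}
  - {id: 13, source: Cs, target: Mb, rate_name: k13, rate_value: 0.3, annotation: homeostatic, efficacy_tier: moderate}
  - {id: 14, source: Ma, target: Mb, rate_name: k14, rate_value: 1.0, annotation: pathogenic,  efficacy_tier: very_high}
  - {id: 15, source: Rs, target: Cs, rate_name: k15, rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 16, source: Ma, target: Cs, rate_name: k16, rate_value: 0.1, annotation: pathogenic,  efficacy_tier: low}
  - {id: 17, source: Ga, target: Rs, rate_name: k17, rate_value: 1.0, annotation: homeostatic, efficacy_tier: very_high}
  - {id: 18, source: Gb, target: Rd, rate_name: k18, rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 19, source: Ma, target: Ga, rate_name: k19, rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 20, source: Mb, target: Gb, rate_name: k20, rate_value: 0.1, annotation: homeostatic, efficacy_tier: low}
  - {id: 21, source: Ga, target: Ma, rate_name: k21, rate_value: 1.0, annotation: homeostatic, efficacy_tier: very_high}
  - {id: 22, source: Ga, target: Mb, rate_name: k22, rate_value: 1.0, annotation: pathogenic,  efficacy_tier: very_high}
reference_sensitivity:
  order: [Rs, Rd, Aa, Ab, Mb, Ma, Cs, Ga, Gb]
  rows:
    Rs: [1, 0, 0, 0, -0.2, 0, 0, 0, 0]
    Rd: [0, 1, 0, 0, 0.2, 0, 0, 0, 0]
    Aa: [0, 0, 1, 0, -0.2, 0, 0, 0, 0]
    Ab: [0, 0, 0, 1, 0.2, 0, 0, 0, 0]
    Mb: [0, 0.3, 0, 0, 1, 0, 0, 0, 0]
    Ma: [0, -0.3, 0, 0, -0.2, 1, 0, 0, 0]
    Cs: [1, 0, 0, 0, -0.2, 0, 1, 0, 0]
    Ga: [0, 0, 1, 0, -0.2, 0, 0, 1, 0]
    Gb: [0, 0, 0, 1, 0.2, 0, 0, 0, 1]
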