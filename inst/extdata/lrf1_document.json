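{
  "doc_id": "lrf1",
  "abstract": [
    "Interactions among LRF-1, JunB, c-Jun, and c-Fos define a regulatory program in the G1 phase of liver regeneration."
  ],
  "sections": [
    {
      "header": "Results",
      "sentences": [
        "Interactions among LRF-1, JunB, c-Jun, and c-Fos define a regulatory program in the G1 phase of liver regeneration.",
        "In regenerating liver, a physiologically normal model of cell growth, LRF-1, JunB, c-Jun, and c-Fos among Jun/Fos/LRF-1 family members are induced posthepatectomy.",
        "In liver cells, high levels of c-Fos/c-Jun, c-Fos/JunB, LRF-1/c-Jun, and LRF-1/JunB complexes are present for several hours after the G0/G1 transition, and the relative level of LRF-1/JunB complexes increases during G1.",
        "We provide evidence for dramatic differences in promoter-specific activation by LRF-1- and c-Fos-containing complexes.",
        "LRF-1 in combination with either Jun protein strongly activates a cyclic AMP response element-containing promoter which c-Fos/Jun does not activate."
      ]
    }
  ]
}
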