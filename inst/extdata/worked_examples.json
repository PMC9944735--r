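{
  "description": "Worked-example sentences from the marine natural products literature with their typed entity mentions. Raw sentences carry Markdown-style emphasis markers as extracted; offsets are recomputed by the package on the normalized text.",
  "examples": [
    {
      "raw": "**Cytotoxic** asterosaponins capable of promoting polymerization of tubulin from the starfish ** *Culcita novaeguineae* **",
      "mentions": [
        {"surface": "Cytotoxic", "etype": "Bioactivity"},
        {"surface": "Culcita", "etype": "Generic_name"},
        {"surface": "novaeguineae", "etype": "Specific_name"}
      ]
    },
    {
      "raw": "Two new steroid glycosides from the far east starfish ** *Hippasteria kurilensis* **",
      "mentions": [
        {"surface": "Hippasteria", "etype": "Generic_name"},
        {"surface": "kurilensis", "etype": "Specific_name"}
      ]
    },
    {
      "raw": "Bromophycolides J-Q (1–8) were isolated from extracts of the Fijian **red alga *Callophycus serratus* ** and identified with 1D and 2D NMR spectroscopy and mass spectral analyses",
      "mentions": [
        {"surface": "Red alga", "etype": "Sample_types"},
        {"surface": "Callophycus serratus", "etype": "Generic_name"}
      ]
    },
    {
      "raw": "As part of our search for bioactive substances from marine organisms systematically and assessing the chemical and biological diversities of seaweeds distributed along the Chinese coast, the **red alga** *Laurencia similis* was collected from **Sanya Bay, Hainan province**",
      "mentions": [
        {"surface": "Red alga", "etype": "Sample_types"},
        {"surface": "Laurencia similis", "etype": "Generic_name"},
        {"surface": "Sanya Bay, Hainan province", "etype": "Sample_source"}
      ]
    },
    {
      "raw": "**Polysiphonia urceolata** was collected **at the coast of Yantai, China**, in May 2008, and identified by Prof. Xiao Fan of the Institute of Oceanology, Chinese Academy of Sciences",
      "mentions": [
        {"surface": "Polysiphonia urceolata", "etype": "Generic_name"},
        {"surface": "At the coast of Yantai, China", "etype": "Sample_source"}
      ]
    }
  ]
}
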