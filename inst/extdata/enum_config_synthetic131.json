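{
  "name": "synthetic131",
  "description": "Synthetic reconstruction of a 131-entry composition database for lyase-depolymerized urinary CS/DS and HS saccharides. The published search space is known only by its size (131 dp compositions); this config spans the product classes the assay observes - 2-AB-labeled and unlabeled internal di- to hexasaccharides and NRE mono- to trisaccharides, split by GAG-class hint where CS/DS and HS products are isobaric - with bounds chosen so the enumeration totals 131 records. It is a stand-in for the unpublished table, suitable for exercising the enumeration and matching machinery, not a transcription of it.",
  "series": [
    {"terminus": "internal", "dp": 2, "acetyl": [1, 1], "so3": [0, 3], "labeled": true,  "gag_class": "CS/DS"},
    {"terminus": "internal", "dp": 2, "acetyl": [1, 1], "so3": [0, 3], "labeled": false, "gag_class": "CS/DS"},
    {"terminus": "internal", "dp": 2, "acetyl": [0, 1], "so3": [0, 3], "labeled": true,  "gag_class": "HS"},
    {"terminus": "internal", "dp": 2, "acetyl": [0, 1], "so3": [0, 3], "labeled": false, "gag_class": "HS"},
    {"terminus": "internal", "dp": 4, "acetyl": [0, 2], "so3": [0, 5], "labeled": true,  "gag_class": "ambiguous"},
    {"terminus": "internal", "dp": 6, "acetyl": [0, 3], "so3": [0, 7], "labeled": true,  "gag_class": "ambiguous"},
    {"terminus": "NRE", "dp": 1, "acetyl": [1, 1], "so3": [0, 2], "labeled": true,  "gag_class": "CS/DS"},
    {"terminus": "NRE", "dp": 1, "acetyl": [0, 0], "so3": [0, 3], "labeled": true,  "gag_class": "HS"},
    {"terminus": "NRE", "dp": 1, "acetyl": [1, 1], "so3": [0, 2], "labeled": true,  "gag_class": "HS"},
    {"terminus": "NRE", "dp": 2, "acetyl": [1, 1], "so3": [0, 3], "labeled": true,  "gag_class": "CS/DS"},
    {"terminus": "NRE", "dp": 2, "acetyl": [0, 0], "so3": [0, 4], "labeled": true,  "gag_class": "HS"},
    {"terminus": "NRE", "dp": 2, "acetyl": [1, 1], "so3": [0, 3], "labeled": true,  "gag_class": "HS"},
    {"terminus": "NRE", "dp": 3, "acetyl": [0, 2], "so3": [0, 4], "labeled": true,  "gag_class": "HS"},
    {"terminus": "NRE", "dp": 2, "acetyl": [1, 1], "so3": [0, 3], "labeled": false, "gag_class": "CS/DS"},
    {"terminus": "NRE", "dp": 1, "acetyl": [1, 1], "so3": [0, 2], "labeled": false, "gag_class": "CS/DS"},
    {"terminus": "NRE", "dp": 3, "acetyl": [0, 2], "so3": [0, 3], "labeled": false, "gag_class": "HS"}
  ]
}
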