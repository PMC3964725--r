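{
  "concepts": [
    {"path": "/DataSets/DataSet/Units/Unit/UnitID", "searchable": true,
     "datatype": "string",
     "value_pool": ["MB.f.1", "MB.f.2", "MB.f.3", "MB.f.4", "MB.f.5",
                    "MB.f.6", "MB.f.7", "MB.f.8"],
     "multiplicity": "single", "presence": 1.0, "distinct_values": true},
    {"path": "/DataSets/DataSet/Units/Unit/Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString",
     "searchable": true, "datatype": "string",
     "value_pool": ["Lepidotes elvensis", "Dapedium punctatum",
                    "Pholidophorus sp."],
     "multiplicity": "single", "presence": 1.0},
    {"path": "/DataSets/DataSet/Units/Unit/PalaeontologicalUnit/Preservation/ChronostratigraphicTerm",
     "searchable": true, "datatype": "string",
     "value_pool": ["Toarcian", "Sinemurian"],
     "multiplicity": "single", "presence": 1.0},
    {"path": "/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI",
     "searchable": false, "datatype": "uri",
     "value_pool": ["http://img.example.org/f1.jpg", "http://img.example.org/f2.jpg"],
     "multiplicity": "single", "presence": 0.5}
  ],
  "n_records": 8,
  "dataset_meta": {"/DataSets/DataSet/Metadata/Description/Representation/Title": "Fossil fishes (synthetic)"},
  "seed": 7,
  "drop_rules": [
    {"concept": "/DataSets/DataSet/Units/Unit/PalaeontologicalUnit/Preservation/ChronostratigraphicTerm",
     "reason": "outside_value_list", "values": ["Sinemurian"]}
  ],
  "repeat_dataset_per_unit": false,
  "last_modified": "2026-09-01"
}
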