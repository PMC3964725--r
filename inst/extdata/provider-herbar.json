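{
  "concepts": [
    {"path": "/DataSets/DataSet/Units/Unit/UnitID", "searchable": true,
     "datatype": "string",
     "value_pool": ["B-10-001", "B-10-002", "B-10-003", "B-10-004", "B-10-005",
                    "B-10-006", "B-10-007", "B-10-008", "B-10-009", "B-10-010",
                    "B-10-011", "B-10-012"],
     "multiplicity": "single", "presence": 1.0, "distinct_values": true},
    {"path": "/DataSets/DataSet/Units/Unit/Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString",
     "searchable": true, "datatype": "string",
     "value_pool": ["Abies alba", "Fagus sylvatica", "Quercus robur",
                    "Picea abies"],
     "multiplicity": "single", "presence": 1.0},
    {"path": "/DataSets/DataSet/Units/Unit/Gathering/Country/Name",
     "searchable": true, "datatype": "string",
     "value_pool": ["Germany", "Austria", "France"],
     "multiplicity": "single", "presence": 0.9},
    {"path": "/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI",
     "searchable": false, "datatype": "uri",
     "value_pool": ["http://img.example.org/1.jpg", "http://img.example.org/2.jpg",
                    "http://img.example.org/3.jpg", "http://img.example.org/4.jpg"],
     "multiplicity": "multi", "presence": 0.8}
  ],
  "n_records": 12,
  "dataset_meta": {"/DataSets/DataSet/Metadata/Description/Representation/Title": "Herbarium Berolinense (synthetic)"},
  "seed": 42,
  "drop_rules": [],
  "repeat_dataset_per_unit": false,
  "last_modified": "2026-08-30"
}
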