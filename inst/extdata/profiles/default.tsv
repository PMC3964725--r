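# Default requirement profile (zoology and botany): readiness for
# ABCD -> ESE/EDM transformation and harvesting.
target_concept	source_paths	mandatory	unique
dc:identifier	/DataSets/DataSet/Units/Unit/UnitID	1	1
dc:title	/DataSets/DataSet/Units/Unit/Identifications/Identification/Result/TaxonIdentified/ScientificName/FullScientificNameString	1	0
europeana:object	/DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI	1	0
dcterms:spatial	/DataSets/DataSet/Units/Unit/Gathering/LocalityText;/DataSets/DataSet/Units/Unit/Gathering/Country/Name	0	0
dc:source	/DataSets/DataSet/Metadata/Description/Representation/Title	0	0
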