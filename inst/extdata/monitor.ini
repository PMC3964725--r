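# Example monitor configuration: two thematic provider groups, three
# data sources served by in-process mock providers.
[general]
cache_interval_days = 7
default_profile = default
profile.default = profiles/default.tsv
profile.mineralogy = profiles/mineralogy.tsv
profile.paleontology = profiles/paleontology.tsv

[group:Herbaria]
herbar.url = mock://herbar
herbar.baseline = 10
herbar.link.portal = http://data.example.org/datasets/resource/14719
herbar.concepts = /DataSets/DataSet/Units/Unit/MultiMediaObjects/MultiMediaObject/FileURI
algae.url = mock://herbar
algae.filter = equals(/DataSets/DataSet/Units/Unit/Gathering/Country/Name,"Germany")

[group:Paleontology]
palfish.url = mock://palfish
palfish.concepts = /DataSets/DataSet/Units/Unit/UnitID
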