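# Obviously fictitious names and places for synthetic fixtures.
given Alexa
given Bobbie
given Casey
given Dana
given Elia
given Frankie
given Gale
given Harley
given Indra
given Jules
given Kit
given Lonnie
family Example
family Fakeson
family Fixture
family Mockwell
family Placeholder
family Sampleton
family Specimen
family Stubbs
family Syntheton
family Testwell
place Exampleton
place Mocktown
place Sampleville
place Stubbington
place Testford
nation Exampleland
nation Mockovia
nation Testonia
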