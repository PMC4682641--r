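[{"shape":"circle","label":"frap","center":[14,14],"radius":4},{"shape":"circle","label":"flip","center":[22,10],"radius":4},{"shape":"circle","label":"nucleus","center":[17,17],"radius":15.5}]
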