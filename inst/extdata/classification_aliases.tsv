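alias	category
missense	missense mutation
frame shift del	frameshift deletion
frame shift ins	frameshift insertion
in frame del	in frame deletion
in frame ins	in frame insertion
start codon del	start codon deletion
start codon ins	start codon insertion
stop codon del	stop codon deletion
stop codon ins	stop codon insertion
nonsense	nonsense mutation
splice site mutation	splice site
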