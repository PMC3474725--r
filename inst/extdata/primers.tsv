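# primer pairs (name, fwd, rev), 5'->3'
nagFCQED	TTCCCAGGAGACAACCCATG	TGAGGCGACAATGAACATGC
COM1	AAAAGAGTTGTACGGCGATG	ACGGTAGAATCCGCGATAGC
PSE1	AAAAGAGCTGTATGGCGAGT	CCGATAGAAGCCACGATAACT
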