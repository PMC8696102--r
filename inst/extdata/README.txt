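Optional real-structure inputs for the test suite.

Place the PDB entry 1LG7 (chain A) here as 1lg7A.pdb to enable the worked
descriptor-example test (MET70: nine contacts, five segments). All other
fixtures are generated programmatically.
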