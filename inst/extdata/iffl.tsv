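#ref	A
# incoherent feed-forward loop: A activates B and C, B inhibits C
A	->	B
A	->	C
B	-|	C
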