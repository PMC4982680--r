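# Ring frameworks of monoterpene skeletons associated with EC-numbered
# synthase products. One SMILES and one family name per line (tab
# separated). Edit freely: entries are canonicalized on load.
C1=CCCCC1	menthane
C1CC2CC(C1)C2	pinane
C1CC2CCC1C2	bornane
C1CC2CC2C1	thujane
C1CCC2CC2C1	carane
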