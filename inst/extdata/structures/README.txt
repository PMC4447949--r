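Place locally downloaded coordinate files here (e.g. 4BNC.pdb, 4AVP.pdb) so
that read_deposited() and the acceptance tests can find them, or point
options(etsface.structure_dir = ...) at another directory. Coordinate entries
are not redistributed with the package.
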