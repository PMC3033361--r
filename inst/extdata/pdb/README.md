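# Deposited-structure fixtures

The worked-example checks compare backbone shapes of a few small deposited
structures. The coordinate files are not redistributed here; to run those
checks, download the entries below from the Protein Data Bank
(https://www.rcsb.org) as legacy PDB format and save them in this directory
with lowercase names before installing the package:

    1mp6.pdb  1g1j.pdb  2k98.pdb  2eow.pdb  1ycc.pdb  1gu2.pdb

All other tests and the acceptance script generate their inputs in code and
need no downloads.
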