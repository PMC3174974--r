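Place optional reference inputs here (not redistributed with the package):

  2QD0.pdb 3TBN.pdb 3TBM.pdb 3TBO.pdb   deposited CISD structures (PDB)
  S2.fasta ... S6.fasta                 published aligned CISD collections

See the top-level README, section "Reference data", for sources. The
structure- and collection-level acceptance tests consume these files; all
other functionality works without them.
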