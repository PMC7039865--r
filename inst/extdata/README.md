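# External data

No data files ship with the package; all test and analysis inputs are
generated in code by the synthetic-trajectory module.

The structure-comparison acceptance test looks here for two user-supplied
Calpha coordinate tables extracted from experimental cryo-EM structures
(they cannot be redistributed with the package):

  5w81_ca.tsv   PDB entry 5W81
  6msm_ca.tsv   PDB entry 6MSM

Format: TSV with a header row and columns `resno`, `x`, `y`, `z`
(coordinates in Angstrom, one CA atom per residue, residue numbering as in
the deposited entry). The test superposes the shared residues and checks
the RMSD.
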