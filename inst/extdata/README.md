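# extdata

The villin headpiece NMR structure (PDB 1VII) is not redistributed with
the package. To run the two native-structure validation checks in
`tests/testthat/test-acceptance.R` (core Phe packing distance and
α-helix count), download it from the RCSB:

    curl -o inst/extdata/1VII.pdb https://files.rcsb.org/download/1VII.pdb

and reinstall the package. Everything else in the test suite builds its
fixtures in code.
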