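Drop-in directory for external data used by the reproduction checks in
tests/testthat/test-acceptance.R. These files are published data that the
package does not redistribute:

  GU191334.gb            GenBank flat file, Equisetum arvense plastome
  GU191333.gb            GenBank flat file, Isoetes flaccida plastome
  additional_file_4.nex  binary indel matrix (NEXUS, CHARSTATELABELS)
  additional_file_5.nex  concatenated gene alignment (NEXUS, 43 taxa)
  additional_file_1.aln  tufA pseudogene pairwise alignment (ClustalW)

With the files absent, the corresponding checks fail with a pointer to
this directory; all other tests are self-contained.
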