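# Replication tally of 74 published GWAS breast cancer hits in an African
# American follow-up, stratified by the ancestry of the discovery GWAS.
# A locus counts as replicated if its hit reached nominal p < 0.05 with a
# consistent direction for overall risk or for its reported ER subtype.
ancestry	n_tested	n_replicated
African	7	5
non-African	67	15
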