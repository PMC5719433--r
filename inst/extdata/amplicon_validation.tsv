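# Amplicon sequence-validation pairs: 13 species assayed by qRT-PCR whose
# ~55-nt PCR products were cloned and re-sequenced. `expected` is the
# RNA-seq-determined sequence, `observed` the cloned product (empty when no
# concordant clone was recovered). The source table concatenates the two
# sequence columns; for rows whose halves differ in length the split is
# inferred: ARF1 (21-nt expected / 17-nt cloned prefix) and miR390b.2
# (21-nt expected / 20-nt cloned product matching the reverse complement
# over a 14-nt run). Cloning orientation is arbitrary, so several matching
# rows are exact reverse complements (miR171d.3, miR390b.1, miR398).
type	name	expected	observed
novel	ARF1	TTCTTGACCTTGTAAGACCTT	TTCTTGACCTTGTAAGA
novel	ARF2	TTCTTGACCTTGTAAGACCCC	TTCTTGACCTTGTAAGACCCC
novel	D8+	CCATACTTTGAATTGTGGAAG	CCATACTTTGAATTGTGGAAG
known	miR168.1	TCGCTTGGTGCAGGTCGGGAA	
half_phase	miR168.2	TGCATCAACTGAATCGGAGAC	TGCATCAACTGAATCGGAGAC
half_phase	miR168.3	TGGATCCCGCCTTGCATCAAC	TGGATCCCGCCTTGCATCAAC
half_phase	miR171d.2	AGATATTGGTGCGGTTCAATC	
half_phase	miR171d.3	TTGTTGTTTGATTGAGCCGTG	CACGGCTCAATCAAACAACAA
known	miR390b.1	AAGCTCAGGAGGGATAGCGCC	GGCGCTATCCCTCCTGAGCTT
half_phase	miR390b.2	CAGGAGGGATAGCGCCATGGA	TCCAGTCGCTATCCCTCCTG
known	miR394c.1	TTGGCATTCTGTCCACCTCC	
phase	miR394c.2	AAGGGTTTCTTACAGAGTTTA	AAGGGTTTCTTACAGAGTTTA
known	miR398	TGTGTTCTCAGGTCGCCCCTG	CAGGGGCGACCTGAGAACACA
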