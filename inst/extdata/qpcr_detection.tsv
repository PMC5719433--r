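# qRT-PCR detection outcomes for the 24 assayed species, by type:
# 10 canonical miRNAs, 6 phased and 8 half-phased miRNA-like RNAs.
# `confirmed` = detected by qRT-PCR (target CT below the no-template control).
type	name	confirmed
canonical	#40	TRUE
canonical	#54	TRUE
canonical	miR394abc	TRUE
canonical	miR168.1	TRUE
canonical	miR390b.1	TRUE
canonical	#28	FALSE
canonical	#44ab	FALSE
canonical	#60.1	FALSE
canonical	miR169b.1	FALSE
canonical	miR171hi	FALSE
phase	miR394c.2	TRUE
phase	#28.2	TRUE
phase	#40.2	TRUE
phase	miR169b.2	FALSE
phase	miR394b.2	FALSE
phase	#60.2	FALSE
half_phase	miR166b.2	TRUE
half_phase	miR168.2	TRUE
half_phase	miR168.3	TRUE
half_phase	miR171d.2	TRUE
half_phase	miR171d.3	TRUE
half_phase	miR390b.2	TRUE
half_phase	#54.2	TRUE
half_phase	#44a.2	FALSE
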