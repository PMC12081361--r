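# Synthetic stand-in compendium of 83 degenerate 16S rRNA primer pairs.
# Oligos are widely used published 16S primers; the pairing into 83
# entries (57 unique, 26 literature-style duplicate listings) is
# synthetic and exists to exercise parsing and deduplication.
set_id	region_tag	forward	reverse	forward_name	reverse_name
V1_P1	V1	AGAGTTTGATCCTGGCTCAG	GACTACHVGGGTATCTAATCC	8F	785R
V1_P2	V1	AGAGTTTGATCMTGGCTCAG	CCGYCAATTYMTTTRAGTTT	27F	926R
V3_P1	V3	CCTACGGGRSGCAGCAG	GGACTACHVGGGTWTCTAAT	U341F	806R
V3_P2	V3	CCTACGGGRSGCAGCAG	CCGYCAATTYMTTTRAGTTT	U341F	926R
V3_P3	V3	ACTCCTACGGGAGGCAGC	GGACTACNVGGGTWTCTAAT	338F	806R2
V1_P3	V1	AGAGTTTGATCCTGGCTCAG	CCGYCAATTYMTTTRAGTTT	8F	926R
V5_P1	V5	AACMGGATTAGATACCCKG	GGGTTGCGCTCGTTG	799F	1100R
V1_P4	V1	AGAGTTTGATCMTGGCTCAG	GACTACHVGGGTATCTAATCC	27F	785R
V3_P4	V3	CCTACGGGRSGCAGCAG	ACGGGCGGTGTGTRC	U341F	1392R
V3_P5	V3	CCTACGGGNGGCWGCAG	CCGYCAATTYMTTTRAGTTT	341F	926R
V3_P6	V3	ACTCCTACGGGAGGCAGC	GGGTTGCGCTCGTTG	338F	1100R
V1_P5	V1	AGAGTTTGATCCTGGCTCAG	GGACTACHVGGGTWTCTAAT	8F	806R
V3_P7	V3	ACTCCTACGGGAGGCAGC	GACTACHVGGGTWTCTAAT	338F	805R
V3_P8	V3	CCTACGGGNGGCWGCAG	TACGGYTACCTTGTTACGACTT	341F	1492R
V1_P6	V1	AGAGTTTGATCMTGGCTCAG	GACTACHVGGGTWTCTAAT	27F	805R
V6_P1	V6	AACGCGAAGAACCTTAC	TACGGYTACCTTGTTACGACTT	968F	1492R
V5_P2	V5	AACMGGATTAGATACCCKG	TACGGYTACCTTGTTACGACTT	799F	1492R
V6_P2	V6	AAACTYAAAKGAATTGACGG	TACGGYTACCTTGTTACGACTT	926F	1492R
V6_P3	V6	AAACTYAAAKGAATTGACGG	ACGGGCGGTGTGTRC	926F	1392R
V1_P7	V1	AGAGTTTGATCMTGGCTCAG	ACGGGCGGTGTGTRC	27F	1392R
V3_P9	V3	CCTACGGGNGGCWGCAG	GACTACHVGGGTATCTAATCC	341F	785R
V1_P8	V1	AGAGTTTGATCMTGGCTCAG	ATTACCGCGGCTGCTGG	27F	534R
V1_P9	V1	AGAGTTTGATCMTGGCTCAG	GACTACHVGGGTATCTAATCC	27F	785R
V1_P10	V1	AGAGTTTGATCMTGGCTCAG	GGACTACHVGGGTWTCTAAT	27F	806R
V4_P1	V4	GTGCCAGCMGCCGCGGTAA	TACGGYTACCTTGTTACGACTT	515F	1492R
V1_P11	V1	AGAGTTTGATCMTGGCTCAG	TACGGYTACCTTGTTACGACTT	27F	1492R
V1_P12	V1	AGAGTTTGATCMTGGCTCAG	CCGYCAATTYMTTTRAGTTT	27F	926R
V1_P13	V1	AGAGTTTGATCCTGGCTCAG	TTACCGCGGCTGCTGGCAC	8F	533R
V6_P4	V6	AACGCGAAGAACCTTAC	GGGTTGCGCTCGTTG	968F	1100R
V1_P14	V1	AGAGTTTGATCMTGGCTCAG	ATTACCGCGGCTGCTGG	27F	534R
V1_P15	V1	AGAGTTTGATCCTGGCTCAG	TACGGYTACCTTGTTACGACTT	8F	1492R
V1_P16	V1	AGAGTTTGATCCTGGCTCAG	TACGGYTACCTTGTTACGACTT	8F	1492R
V1_P17	V1	AGAGTTTGATCCTGGCTCAG	GACTACHVGGGTATCTAATCC	8F	785R
V1_P18	V1	AGAGTTTGATCMTGGCTCAG	CRRCACGAGCTGACGAC	27F	1061R
V3_P10	V3	CCTACGGGRSGCAGCAG	ACGGGCGGTGTGTRC	U341F	1392R
V3_P11	V3	CCTACGGGNGGCWGCAG	GACTACHVGGGTATCTAATCC	341F	785R
V5_P3	V5	AACMGGATTAGATACCCKG	CRRCACGAGCTGACGAC	799F	1061R
V3_P12	V3	CCTACGGGNGGCWGCAG	CCGYCAATTYMTTTRAGTTT	341F	926R
V4_P2	V4	GTGYCAGCMGCCGCGGTAA	CRRCACGAGCTGACGAC	515FB	1061R
V4_P3	V4	GTGYCAGCMGCCGCGGTAA	CCGYCAATTYMTTTRAGTTT	515FB	926R
V5_P4	V5	AGGATTAGATACCCTGGTA	GGGTTGCGCTCGTTG	784F	1100R
V3_P13	V3	CCTACGGGNGGCWGCAG	GGACTACHVGGGTWTCTAAT	341F	806R
V3_P14	V3	CCTACGGGNGGCWGCAG	CRRCACGAGCTGACGAC	341F	1061R
V1_P19	V1	AGAGTTTGATCMTGGCTCAG	GGACTACHVGGGTWTCTAAT	27F	806R
V3_P15	V3	CCTACGGGRSGCAGCAG	GGACTACNVGGGTWTCTAAT	U341F	806R2
V1_P20	V1	AGAGTTTGATCCTGGCTCAG	GGGTTGCGCTCGTTG	8F	1100R
V4_P4	V4	GTGCCAGCMGCCGCGGTAA	CRRCACGAGCTGACGAC	515F	1061R
V6_P5	V6	AAACTYAAAKGAATTGACGG	TACGGYTACCTTGTTACGACTT	926F	1492R
V6_P6	V6	AAACTYAAAKGAATTGACGG	ACGGGCGGTGTGTRC	926F	1392R
V1_P21	V1	AGAGTTTGATCCTGGCTCAG	GACTACHVGGGTWTCTAAT	8F	805R
V3_P16	V3	ACTCCTACGGGAGGCAGC	ACGGGCGGTGTGTRC	338F	1392R
V3_P17	V3	ACTCCTACGGGAGGCAGC	GACTACHVGGGTWTCTAAT	338F	805R
V3_P18	V3	CCTACGGGNGGCWGCAG	GGGTTGCGCTCGTTG	341F	1100R
V3_P19	V3	CCTACGGGNGGCWGCAG	ACGGGCGGTGTGTRC	341F	1392R
V3_P20	V3	CCTACGGGNGGCWGCAG	ACGGGCGGTGTGTRC	341F	1392R
V3_P21	V3	ACTCCTACGGGAGGCAGC	GACTACHVGGGTATCTAATCC	338F	785R
V3_P22	V3	CCTACGGGNGGCWGCAG	GGGTTGCGCTCGTTG	341F	1100R
V4_P5	V4	GTGYCAGCMGCCGCGGTAA	CCGYCAATTYMTTTRAGTTT	515FB	926R
V3_P23	V3	ACTCCTACGGGAGGCAGC	GACTACHVGGGTATCTAATCC	338F	785R
V3_P24	V3	ACTCCTACGGGAGGCAGC	ACGGGCGGTGTGTRC	338F	1392R
V3_P25	V3	ACTCCTACGGGAGGCAGC	GGACTACNVGGGTWTCTAAT	338F	806R2
V4_P6	V4	GTGCCAGCMGCCGCGGTAA	GGGTTGCGCTCGTTG	515F	1100R
V1_P22	V1	AGAGTTTGATCMTGGCTCAG	TGCTGCCTCCCGTAGGAGT	27F	338R
V4_P7	V4	GTGYCAGCMGCCGCGGTAA	GGGTTGCGCTCGTTG	515FB	1100R
V1_P23	V1	AGAGTTTGATCCTGGCTCAG	CCGYCAATTYMTTTRAGTTT	8F	926R
V1_P24	V1	AGAGTTTGATCCTGGCTCAG	ATTACCGCGGCTGCTGG	8F	534R
V4_P8	V4	GTGCCAGCMGCCGCGGTAA	CCGYCAATTYMTTTRAGTTT	515F	926R
V5_P5	V5	AGGATTAGATACCCTGGTA	ACGGGCGGTGTGTRC	784F	1392R
V3_P26	V3	CCTACGGGRSGCAGCAG	GGGTTGCGCTCGTTG	U341F	1100R
V1_P25	V1	AGAGTTTGATCCTGGCTCAG	GGGTTGCGCTCGTTG	8F	1100R
V3_P27	V3	CCTACGGGRSGCAGCAG	CCGYCAATTYMTTTRAGTTT	U341F	926R
V4_P9	V4	GTGCCAGCMGCCGCGGTAA	CCGYCAATTYMTTTRAGTTT	515F	926R
V4_P10	V4	GTGYCAGCMGCCGCGGTAA	TACGGYTACCTTGTTACGACTT	515FB	1492R
V6_P7	V6	AACGCGAAGAACCTTAC	TACGGYTACCTTGTTACGACTT	968F	1492R
V6_P8	V6	AAACTYAAAKGAATTGACGG	GGGTTGCGCTCGTTG	926F	1100R
V1_P26	V1	AGAGTTTGATCCTGGCTCAG	GGACTACNVGGGTWTCTAAT	8F	806R2
V1_P27	V1	AGAGTTTGATCCTGGCTCAG	TGCTGCCTCCCGTAGGAGT	8F	338R
V1_P28	V1	AGAGTTTGATCMTGGCTCAG	GGACTACNVGGGTWTCTAAT	27F	806R2
V1_P29	V1	AGAGTTTGATCCTGGCTCAG	CRRCACGAGCTGACGAC	8F	1061R
V4_P11	V4	GTGYCAGCMGCCGCGGTAA	GGGTTGCGCTCGTTG	515FB	1100R
V4_P12	V4	GTGCCAGCMGCCGCGGTAA	GGGTTGCGCTCGTTG	515F	1100R
V4_P13	V4	GTGYCAGCMGCCGCGGTAA	CRRCACGAGCTGACGAC	515FB	1061R
V3_P28	V3	CCTACGGGRSGCAGCAG	TACGGYTACCTTGTTACGACTT	U341F	1492R
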