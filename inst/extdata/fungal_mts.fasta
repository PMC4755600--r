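>Ncrassa_MT UniProtKB P02807 Neurospora crassa metallothionein
MGDCGCSGASSCNCGSGCSCSNCGSK
>Cglabrata_MT1 UniProtKB P15113 Candida glabrata metallothionein 1
MANDCKCPNGCSCPNCANGGCQCGDKCECKKQSCHGCGEQCKCGSHGSSCHGSCGCGDKCECK
>Cglabrata_MT2 UniProtKB P15114 Candida glabrata metallothionein 2
MPEQVNCQYDCHCSNCACENTCNCCAKPACACTNSASNECSCQTCKCQTCKC
>Ylipolytica_MT3 UniProtKB Q9HFD0 Yarrowia lipolytica metallothionein 3
MEFTTAMLGASLISTTSTQSKHNLVNNCCCSSSTSESSMPASCACTKCGCKTCKC
>Scerevisiae_Cup1 UniProtKB P0CX80 Saccharomyces cerevisiae Cup1
MFSELINFQNEGHECQCQCGSCKNNEQCQKSCSCPTGCNSDDKCPCGNKSEETKKSCCSGK
>Scerevisiae_Crs5 UniProtKB P41902 Saccharomyces cerevisiae Crs5
MTVKICDCEGECCKDSCHCGSTCLPSCSGGEKCKCDHSTGSPQCKSCGEKCKCETTCTCEKSKCNCEKC
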