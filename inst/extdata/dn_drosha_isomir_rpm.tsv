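mature_id	sequence	offset5	length_nt	mean_rpm_control	mean_rpm_case	printed_digits
miR-183-5p	UGUAUGGCACUGGUAGAAUUCACU	2	24	4.653	50.75	1
miR-183-5p	GUAUGGCACUGGUAGAAUUCACU	1	23	1.338	9.896	1
miR-183-5p	UAUGGCACUGGUAGAAUUCACU	0	22	1566	2122	1
miR-183-5p	AUGGCACUGGUAGAAUUCACU	-1	21	353.5	543.1	1
miR-182-5p	UUUUGGCAAUGGUAGAACUCACACU	1	25	0	0	NA
miR-182-5p	UUUGGCAAUGGUAGAACUCACACU	0	24	1486	1468	1
miR-182-5p	UUGGCAAUGGUAGAACUCACACU	-1	23	0	0	NA
miR-96-5p	UUUUGGCACUAGCACAUUUUUGCU	1	24	1.218	6.41	1
miR-96-5p	UUUGGCACUAGCACAUUUUUGCU	0	23	612.9	619	1
miR-96-5p	UUGGCACUAGCACAUUUUUGCU	-1	22	0	0	NA
miR-21-5p	GUAGCUUAUCAGACUGAUGUUGA	1	23	0	0	NA
miR-21-5p	UAGCUUAUCAGACUGAUGUUGA	0	22	2641.9	223.6	2
miR-21-5p	AGCUUAUCAGACUGAUGUUGA	-1	21	0	0	NA
miR-10a-5p	AUACCCUGUAGAUCCGAAUUUGUG	1	24	0	0	NA
miR-10a-5p	UACCCUGUAGAUCCGAAUUUGUG	0	23	6310.2	4760.9	2
miR-10a-5p	ACCCUGUAGAUCCGAAUUUGUG	-1	22	9750.7	2808.1	2
miR-34a-5p	UUGGCAGUGUCUUAGCUGGUUGU	1	23	0	0	NA
miR-34a-5p	UGGCAGUGUCUUAGCUGGUUGU	0	22	10359.8	6107.3	2
miR-34a-5p	GGCAGUGUCUUAGCUGGUUGU	-1	21	204.5	0	NA
miR-105-5p	GUCAAAUGCUCAGACUCCUGUGGU	1	24	0	0	NA
miR-105-5p	UCAAAUGCUCAGACUCCUGUGGU	0	23	717.2	36.5	3
miR-105-5p	CAAAUGCUCAGACUCCUGUGGU	-1	22	99.6	1.3	3
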