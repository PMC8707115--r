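taxon	source	diploid_number	haploid_number	status
Acromyrmex ambiguus	B28; B29	38		diploid_consistent
Acromyrmex ameliae	B30	36		diploid_consistent
Acromyrmex aspersus	B31	38		diploid_consistent
Acromyrmex balzani	B32; B33	38		diploid_consistent
Acromyrmex coronatus	B32	38	19	diploid_consistent
Acromyrmex crassispinus	B29; B34	38		diploid_consistent
Acromyrmex disciger	B32	38		diploid_consistent
Acromyrmex echinatior	B32	38		diploid_consistent
Acromyrmex heyeri	B28; B35	38		diploid_consistent
Acromyrmex hispidus	B28	38		diploid_consistent
Acromyrmex lundi	B29	38	19	diploid_consistent
Acromyrmex niger	B32	38		diploid_consistent
Acromyrmex nigrosetosus	B29	38	19	diploid_consistent
Acromyrmex rugosus	B32	38		diploid_consistent
Acromyrmex subterraneus molestans	B31; B34	38		diploid_consistent
Acromyrmex subterraneus subterraneus	B29; B34	38		diploid_consistent
Acromyrmex subterraneus brunneus	B30	38		diploid_consistent
Amoimyrmex striatus	B11	22		diploid_consistent
Amoimyrmex silvestrii	B36	22		diploid_consistent
Amoimyrmex bruchi	B36	22		diploid_consistent
Apterostigma madidiense	B37		23	diploid_consistent
Apterostigma madidiense	This study	24		diploid_consistent
Apterostigma mayri	B38	24		diploid_consistent
Apterostigma sp.	B34	20		diploid_consistent
Apterostigma sp.	B38	24		diploid_consistent
Apterostigma sp.	B39	32		diploid_consistent
Apterostigma steigeri	B37	22		diploid_consistent
Atta bisphaerica	B34; B40	22		diploid_consistent
Atta colombica	B38	22	11	diploid_consistent
Atta laevigata	B34; B40	22		diploid_consistent
Atta robusta	B41	22		diploid_consistent
Atta sexdens	B34; B35; B40	22		diploid_consistent
Atta sexdens	B33	22		diploid_consistent
Cyphomyrmex cornutus	B39	22		diploid_consistent
Cyphomyrmex costatus	B38	20		diploid_consistent
Cyphomyrmex rimosus	B38	32		diploid_consistent
Cyphomyrmex transversus	B33	24	12	diploid_consistent
Cyphomyrmex transversus	This study	42	21	diploid_consistent
Mycetarotes carinatus	B42	14		diploid_consistent
Mycetarotes parallelus	B42	54		inconsistent
Mycetomoellerius fuscus	B43	18	9	diploid_consistent
Mycetomoellerius holmgreni	B7	20	10	diploid_consistent
Mycetomoellerius iheringi	B44	20	10	diploid_consistent
Mycetomoellerius relictus	B37	20	10	diploid_consistent
Mycetomoellerius sp.	B37	22		diploid_consistent
Mycetophylax conformis	B10	30	15	diploid_consistent
Mycetophylax morschi	B10	30	15	inconsistent
Mycetophylax morschi	B10	26	13	inconsistent
Mycetophylax morschi	B17	28	14	diploid_consistent
Mycetophylax simplex	B10	36	18	diploid_consistent
Mycocepurus goeldii	B45	8		diploid_consistent
Mycocepurus goeldii	This study	8	4	diploid_consistent
Mycocepurus sp.	B38	8		haploid_consistent
Myrmicocrypta sp.	B33	30		diploid_consistent
Myrmicocrypta sp.	This study	28	14	diploid_consistent
Sericomyrmex amabilis	B38	50		diploid_consistent
Sericomyrmex sp.	B37	50	25	diploid_consistent
Sericomyrmex parvulus	This study	50	25	diploid_consistent
Trachymyrmex septentrionalis	B38	20	10	diploid_consistent
Trachymyrmex sp.1	B38	12	6	diploid_consistent
Trachymyrmex sp.2	B38	18		diploid_consistent
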