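(((Mycocepurus_goeldii:15,Mycocepurus_sp.:15):35,(Myrmicocrypta_sp.:47,(Apterostigma_steigeri:45,(Apterostigma_mayri:20,Apterostigma_madidiense:20):25):2):3):5,((Mycetophylax_simplex:20,(Mycetophylax_conformis:10,Mycetophylax_morschi:10):10):28,((Mycetarotes_carinatus:30,Mycetarotes_parallelus:30):15,(((Cyphomyrmex_costatus:19,Cyphomyrmex_rimosus:19):6,(Cyphomyrmex_cornutus:18,Cyphomyrmex_transversus:18):7):15,((Sericomyrmex_amabilis:5,(Sericomyrmex_parvulus:3,Sericomyrmex_sp.:3):2):30,(((Trachymyrmex_septentrionalis:16.8,(Trachymyrmex_sp.1:10,Trachymyrmex_sp.2:10):6.8):9.2,(Mycetomoellerius_fuscus:24.8,(Mycetomoellerius_sp.:20,(Mycetomoellerius_holmgreni:12,(Mycetomoellerius_iheringi:8,Mycetomoellerius_relictus:8):4):8):4.8):1.2):4,((Amoimyrmex_striatus:4.7,(Amoimyrmex_silvestrii:2,Amoimyrmex_bruchi:2):2.7):13.3,((Atta_bisphaerica:13.7,(Atta_colombica:10,(Atta_laevigata:7,(Atta_robusta:4,Atta_sexdens:4):3):3):3.7):2.3,(Acromyrmex_ameliae:10,(Acromyrmex_ambiguus:8,Acromyrmex_aspersus:8,Acromyrmex_balzani:8,Acromyrmex_coronatus:8,Acromyrmex_crassispinus:8,Acromyrmex_disciger:8,Acromyrmex_echinatior:8,Acromyrmex_heyeri:8,Acromyrmex_hispidus:8,Acromyrmex_lundi:8,Acromyrmex_niger:8,Acromyrmex_nigrosetosus:8,Acromyrmex_rugosus:8,Acromyrmex_subterraneus_molestans:8,Acromyrmex_subterraneus_subterraneus:8,Acromyrmex_subterraneus_brunneus:8):2):6):2):12):5):5):5):3):7);
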