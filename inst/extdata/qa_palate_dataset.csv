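group,subgroup,feeding_habit,species,palate_length_gm,palate_width_gm,zygomatic_gm,q_count,a_count,qa_ratio
bats,phyllostomid,carnivory,Chrotopterus auritus,0.71,0.62,1.10,23,17,1.35
bats,phyllostomid,frugivory,Artibeus glaucus,0.64,0.75,1.10,20,10,2.00
bats,phyllostomid,frugivory,Artibeus gnomus,0.60,0.78,1.11,21,10,2.10
bats,phyllostomid,frugivory,Artibeus jamaicensis,0.70,0.76,1.11,23,13,1.77
bats,phyllostomid,frugivory,Artibeus lituratus,0.67,0.80,1.10,23,10,2.30
bats,phyllostomid,frugivory,Artibeus obscurus,0.68,0.77,1.12,23,13,1.77
bats,phyllostomid,frugivory,Artibeus watsoni,0.63,0.75,1.06,21,9,2.33
bats,phyllostomid,frugivory,Carollia perspicillata,0.73,0.63,1.07,19,15,1.27
bats,phyllostomid,frugivory,Carollia subrupha,0.74,0.63,1.04,18,14,1.29
bats,phyllostomid,frugivory,Chiroderma doriae,0.72,0.79,1.12,26,13,2.00
bats,phyllostomid,frugivory,Chiroderma villosum,0.74,0.80,1.11,23,12,1.92
bats,phyllostomid,frugivory,Rhinophylla fisherae,0.69,0.67,1.09,20,14,1.43
bats,phyllostomid,frugivory,Rhinophylla pumilio,0.68,0.67,1.07,17,13,1.31
bats,phyllostomid,frugivory,Sturnira lilium,0.63,0.67,1.18,20,12,1.67
bats,phyllostomid,frugivory,Sturnira tildae,0.66,0.68,1.21,17,14,1.21
bats,phyllostomid,frugivory,Vampyressa pusilla,0.67,0.78,1.11,23,13,1.77
bats,phyllostomid,frugivory,Vampyrodes caraccioli,0.71,0.82,1.14,21,13,1.62
bats,phyllostomid,strict frugivory,Pygoderma bilabiatum,0.54,0.69,1.27,22,11,2.00
bats,phyllostomid,hematophagy,Desmodus rotundus,0.44,0.60,1.24,18,12,1.50
bats,phyllostomid,hematophagy,Diphylla ecaudata,0.51,0.62,1.23,19,13,1.46
bats,phyllostomid,insectivory,Glyphonicteris sylvestris,0.81,0.64,1.03,20,15,1.33
bats,phyllostomid,nectarivory,Anoura caudifer,0.90,0.51,0.99,21,14,1.50
bats,phyllostomid,nectarivory,Anoura geoffroyi,0.91,0.52,0.99,19,14,1.36
bats,phyllostomid,nectarivory,Glossophaga commissarisi,0.85,0.54,0.99,21,15,1.40
bats,phyllostomid,nectarivory,Glossophaga soricina,0.86,0.54,0.99,20,14,1.43
bats,phyllostomid,nectarivory,Lonchophylla thomasi,0.83,0.54,1.00,18,15,1.20
bats,phyllostomid,omnivory,Lophostoma silviculum,0.77,0.60,1.04,19,15,1.27
bats,phyllostomid,omnivory,Mimon benettii,0.75,0.66,1.07,17,13,1.31
bats,phyllostomid,omnivory,Gardnerycteris crenulatum,0.72,0.69,1.01,17,15,1.13
bats,phyllostomid,omnivory,Phylostomus elongatus,0.75,0.70,1.09,19,15,1.27
bats,phyllostomid,omnivory,Phylostomus hastatus,0.74,0.63,1.09,19,14,1.36
primates,NWM,unspecified,Leontopithecus rosalia,0.77,0.52,1.26,23,17,1.35
primates,NWM,unspecified,Sapajus robustus,0.80,0.42,1.40,21,16,1.31
primates,NWM,unspecified,Brachytheles arachnoides,0.80,0.42,1.34,21,16,1.31
primates,NWM,unspecified,Callithrix hummelifera,0.72,0.51,1.32,21,17,1.24
primates,NWM,unspecified,Callithrix pygmaea,0.72,0.47,1.26,19,16,1.19
primates,NWM,unspecified,Callithrix geoffroyi,0.74,0.49,1.29,21,17,1.24
primates,OWM,unspecified,Pan paniscus,0.73,0.51,1.33,16,17,0.94
primates,OWM,unspecified,Pan troglodites,0.75,0.51,1.29,25,17,1.47
primates,OWM,unspecified,Macaca fasciculari,0.88,0.49,1.32,24,17,1.41
primates,OWM,unspecified,Gorilla gorilla,0.75,0.46,1.25,22,17,1.29
primates,OWM,unspecified,Homo sapiens,0.60,0.47,1.26,23,17,1.35
primates,OWM,unspecified,Homo neanderthalensis,0.63,0.49,1.38,23,17,1.35
primates,OWM,unspecified,Papio anubis,0.94,0.47,1.23,24,17,1.41
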