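# Per-taxon evidence stated in the source survey's Results/Discussion prose
# but not carried by its printed tables: cluster-sharing with nominal
# species, intraspecific divergence of open-nomenclature taxa, per-method
# cluster counts where they depart from the BIN count, and cluster
# exclusivity for taxa absent from the undescribed-species table.
# NA = not stated / derive from the transcribed tables.
morphospecies	max_intra	n_bin	n_abgd	n_bptp	n_exclusive	shares_nominal	shares_any	note
Astyanax fasciatus	NA	NA	NA	NA	NA	TRUE	TRUE	clusters comprise other Astyanax species
Astyanax lacustris	NA	NA	NA	NA	NA	TRUE	TRUE	in cluster with another nominal species
Astyanax scabripinnis	NA	NA	NA	NA	NA	TRUE	TRUE	in cluster with another nominal species
Astyanax taeniatus	NA	NA	NA	NA	NA	TRUE	TRUE	in cluster with another nominal species
Crenicichla lacustris	NA	NA	NA	NA	NA	FALSE	FALSE	two exclusive clusters, congruent methods
Hoplias malabaricus	NA	NA	NA	NA	NA	FALSE	FALSE	two exclusive clusters, congruent methods
Knodus moenkhausii	NA	NA	NA	NA	NA	FALSE	FALSE	single clade and cluster in two methods
Poecilia reticulata	NA	NA	NA	NA	NA	TRUE	TRUE	shares cluster with Poecilia vivipara
Prochilodus costatus	NA	NA	NA	NA	NA	TRUE	TRUE	in clusters with other Prochilodus species
Rhamdia cf. quelen	NA	NA	NA	NA	2	FALSE	FALSE	two exclusive congruent clusters
Trichomycterus aff. alternatus	NA	NA	NA	NA	0	TRUE	TRUE	in cluster with Trichomycterus longibarbatus
Trichomycterus aff. immaculatus	NA	NA	NA	NA	0	TRUE	TRUE	in cluster with another nominal species
Characidium gr. timbuiense	9.9	3	3	3	1	FALSE	TRUE	two mixed clades with Characidium sp. plus one exclusive clade
Astyanax sp.	20.5	NA	NA	NA	NA	NA	NA	deep within-label divergence
Characidium sp.	10.17	NA	NA	NA	NA	NA	NA	deep within-label divergence
Gymnotus sp.	6.32	NA	NA	NA	NA	NA	NA	deep within-label divergence
Harttia sp.	12.2	NA	3	1	NA	NA	NA	three BIN and ABGD clusters, one bPTP cluster
Trichomycterus sp.	NA	NA	4	5	NA	NA	NA	ABGD pools two BIN pairs across the label complex
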