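# Morphospecies with deep (>2%) intraspecific divergence: maximum and mean
# intraspecific K2P distance (%), number of tree clades and of BIN / ABGD /
# bPTP clusters, transcribed from the source survey's published table.
# `starred` marks taxa the survey flagged for congruent hidden diversity.
# The combined row pools two labels separated by '/'.
species	max_intra	mean_intra	n_clades	n_bin	n_abgd	n_bptp	starred
Astyanax fasciatus	20.69	10.09	3	3	3	3	FALSE
Astyanax lacustris	3.35	1.67	2	2	2	2	FALSE
Astyanax scabripinnis	21.82	9.12	2	2	3	2	FALSE
Astyanax taeniatus	3.96	1.48	2	2	2	2	FALSE
Characidium sp./Characidium cf. timbuiense	10.17/9.9	5.51/5.98	4	4	4	4	TRUE
Crenicichla lacustris	21.36	10.76	2	2	2	2	TRUE
Hoplias malabaricus	6.7	3.27	2	2	2	2	TRUE
Knodus moenkhausii	3.07	1.21	1	1	2	1	FALSE
Poecilia reticulata	14.34	9.48	2	2	2	2	FALSE
Prochilodus costatus	2.6	1.32	2	1	1	2	FALSE
Rhamdia cf. quelen	3.48	1.25	2	2	2	2	TRUE
Trichomycterus aff. alternatus	18.49	10.8	2	2	2	2	FALSE
Trichomycterus aff. immaculatus	5.84	2.23	2	2	2	2	FALSE
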