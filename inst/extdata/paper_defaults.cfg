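# Reference analysis profile: rarefaction depth 500, 999 permutations,
# 90% bootstrap fraction, 999 bootstrap replicates, co-occurrence
# threshold |rho| > 0.5, rank sweep from ASVs up to order.
depth = 500
n_perm = 999
n_boot = 999
frac = 0.9
rho_threshold = 0.5
rank_levels = asv,genus,family,order
term_order = sample_type,tissue_storage,extraction_kit,host_class,host_order,host_species
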