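# Small synthetic run used by the README worked example and the
# byte-identical re-run check; finishes in well under a minute.
n_species = 10
samples_per_species = 5
n_features_per_kingdom = 60
sim_depth = 1500
phylo_strength = 1.2
coupling = 0.7
sigma_within = 0.5
batch_effect_size = 0.4
diet_signal = 0.7
depth = 500
n_perm = 199
n_boot = 199
frac = 0.9
rho_threshold = 0.5
rank_levels = asv,family
term_order = sample_type,tissue_storage,extraction_kit,host_class,host_species
min_samples = 5
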