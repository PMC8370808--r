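## Pipeline orchestration: flat key=value configs, staged execution
## with a machine-readable manifest, and a markdown report.

PIPELINE_STAGES <- c("ingest", "normalize", "diversity_signal", "permanova",
                     "phylosymbiosis", "procrustes", "diet", "networks")

#' Default run configuration
#'
#' Encodes the reference analysis profile: rarefaction depth 500, 999
#' permutations, 90% bootstrap fraction with 999 replicates, co-occurrence
#' threshold |rho| > 0.5, rank sweep asv/genus/family/order, and the
#' term order sample type, tissue storage, extraction kit, class,
#' order, species (batch factors marginalized before host taxonomy).
#'
#' @param ... overrides of default entries.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    input_dir = NA_character_,       # if NA, simulate
    n_species = 12L, samples_per_species = 6L,
    n_features_per_kingdom = 80L, sim_depth = 2000L,
    phylo_strength = 1, coupling = 0.6, sigma_within = 0.5,
    batch_effect_size = 0.4, n_batch_levels = 3L, diet_signal = 0.7,
    depth = 500L,
    pseudocount_rule = "unit",
    term_order = c("sample_type", "tissue_storage", "extraction_kit",
                   "host_class", "host_order", "host_species"),
    rank_levels = c("asv", "genus", "family", "order"),
    frac = 0.9, n_boot = 999L, n_perm = 999L,
    rho_threshold = 0.5, min_prevalence = 0.2, min_samples = 5L,
    seed = NA_integer_,
    outdir = NA_character_
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort("unknown config key(s): ", paste(unknown, collapse = ", "),
                             class = "phylosym_argument_error")
  cfg[names(over)] <- over
  if (is.na(cfg$seed)) abort("config requires an explicit seed",
                             class = "phylosym_argument_error")
  if (!length(cfg$term_order)) abort("term_order must be non-empty")
  cfg$seed <- check_scalar_int(cfg$seed, "seed", 0L)
  class(cfg) <- "run_config"
  cfg
}

#' Read a flat key=value config file
#'
#' Lines are `key = value`; list values are comma-separated; `#`
#' comments and blank lines are ignored.  Unknown keys are an error.
#'
#' @param path config file path.
#' @param ... further overrides applied after the file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 1L) < 2L]
  if (length(bad)) abort("malformed config line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) {
      if (all(num == round(num))) as.integer(num) else num
    } else parts
  }
  parsed <- stats::setNames(lapply(vals, parse_val), keys)
  do.call(run_config, utils::modifyList(parsed, list(...)))
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

sweep_to_df <- function(sweep, kingdom = NA_character_) {
  do.call(rbind, lapply(sweep, function(s) {
    data.frame(kingdom = kingdom, rank = s$rank, correlation = s$correlation,
               ci_lower = s$interval[1], ci_upper = s$interval[2],
               frac = s$frac, n_boot = s$n_boot, stringsAsFactors = FALSE)
  }))
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: ingest (or simulate), normalize (rarefy +
#' CLR), diversity and phylogenetic signal, sequential PERMANOVA per
#' kingdom, phylosymbiosis sweep per kingdom, cross-kingdom
#' Procrustes/PROTEST with bootstrap sweep, diet analysis, and
#' co-occurrence networks.  Results are TSV files in `config$outdir`
#' plus a JSON `manifest.json` (config echo, package version, per-file
#' md5 hashes, warnings).  Identical config implies byte-identical
#' outputs.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to execute (ingest and normalize are
#'   always run since every stage depends on them); default all.
#' @return the manifest, invisibly.
#' @export
run_all <- function(config, stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- union(stages, c("ingest", "normalize"))
  outdir <- config$outdir
  if (is.na(outdir)) abort("config$outdir is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  outputs <- character(0)
  emit <- function(df, name, type) {
    path <- file.path(outdir, name)
    write_tsv_schema(df, path, type)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    pipeline_log("stage %s ...", name)
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "phylosym_stage_error")
    })
    pipeline_log("stage %s done (%.1fs)", name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  ## -- ingest -------------------------------------------------------------
  ds <- stage("ingest", {
    if (!is.na(config$input_dir)) {
      dirp <- config$input_dir
      list(
        fungi = read_feature_table(file.path(dirp, "fungi_counts.tsv"), "fungi"),
        bacteria = read_feature_table(file.path(dirp, "bacteria_counts.tsv"), "bacteria"),
        taxonomy_fungi = read_taxonomy(file.path(dirp, "fungi_taxonomy.tsv")),
        taxonomy_bacteria = read_taxonomy(file.path(dirp, "bacteria_taxonomy.tsv")),
        metadata = read_metadata(file.path(dirp, "metadata.tsv")),
        diet = if (file.exists(file.path(dirp, "diet.tsv"))) {
          read_diet(file.path(dirp, "diet.tsv"))
        } else NULL,
        tree = read_newick(file.path(dirp, "host_tree.nwk"))
      )
    } else {
      tree <- simulate_host_tree(config$n_species, config$seed)
      sim <- simulate_paired_microbiome(tree, simulation_config(
        n_species = config$n_species,
        samples_per_species = config$samples_per_species,
        n_features_per_kingdom = config$n_features_per_kingdom,
        depth = config$sim_depth, phylo_strength = config$phylo_strength,
        coupling = config$coupling, sigma_within = config$sigma_within,
        batch_effect_size = config$batch_effect_size,
        n_batch_levels = config$n_batch_levels,
        diet_signal = config$diet_signal, seed = config$seed))
      write_simulated_dataset(sim, file.path(outdir, "simulated_input"))
      outputs <- c(outputs, list.files(file.path(outdir, "simulated_input"),
                                       full.names = TRUE))
      sim
    }
  })
  validate_alignment(ds$fungi, ds$metadata, ds$taxonomy_fungi)
  validate_alignment(ds$bacteria, ds$metadata, ds$taxonomy_bacteria)

  ## -- normalize ----------------------------------------------------------
  norm <- stage("normalize", {
    rf <- rarefy(ds$fungi, config$depth, config$seed + 11L)
    rb <- rarefy(ds$bacteria, config$depth, config$seed + 12L)
    for (kg in c("fungi", "bacteria")) {
      dr <- attr(if (kg == "fungi") rf else rb, "dropped_samples")
      if (length(dr)) note(sprintf("rarefy dropped %s samples: %s", kg,
                                   paste(dr, collapse = ",")))
    }
    list(rare_fungi = rf, rare_bacteria = rb,
         clr_fungi = clr_transform(ds$fungi, config$pseudocount_rule),
         clr_bacteria = clr_transform(ds$bacteria, config$pseudocount_rule))
  })
  emit(data.frame(sample_id = rownames(norm$clr_fungi),
                  unclass(norm$clr_fungi), check.names = FALSE),
       "clr_fungi.tsv", "clr_matrix")
  emit(data.frame(sample_id = rownames(norm$clr_bacteria),
                  unclass(norm$clr_bacteria), check.names = FALSE),
       "clr_bacteria.tsv", "clr_matrix")

  ## -- diversity + phylogenetic signal -------------------------------------
  if ("diversity_signal" %in% stages) stage("diversity_signal", {
    af <- alpha_diversity(norm$rare_fungi)
    ab <- alpha_diversity(norm$rare_bacteria)
    emit(af, "alpha_fungi.tsv", "alpha_diversity")
    emit(ab, "alpha_bacteria.tsv", "alpha_diversity")
    emit(paired_richness_summary(af, ab, ds$metadata),
         "paired_richness.tsv", "paired_richness_summary")
    ## species-mean traits on the host tree
    species_mean <- function(alpha, col) {
      sp <- ds$metadata$host_species[match(alpha$sample_id, ds$metadata$sample_id)]
      tapply(alpha[[col]], sp, mean)
    }
    combos <- expand.grid(kingdom = c("fungi", "bacteria"),
                          trait = c("observed_richness", "shannon"),
                          stringsAsFactors = FALSE)
    res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
      alpha <- if (combos$kingdom[i] == "fungi") af else ab
      tr <- species_mean(alpha, combos$trait[i])
      tr <- tr[ds$tree$tip.label[ds$tree$tip.label %in% names(tr)]]
      tree_i <- if (length(tr) < length(ds$tree$tip.label)) {
        ape::keep.tip(ds$tree, names(tr))
      } else ds$tree
      cbind(kingdom = combos$kingdom[i],
            abouheif_test(tr, tree_i, n_perm = config$n_perm,
                          seed = config$seed + 20L + i,
                          trait_name = combos$trait[i]))
    }))
    res$p_bh <- bh_correct(res$p_raw)
    emit(res, "phylo_signal.tsv", "signal_tests")
  })

  ## -- PERMANOVA ----------------------------------------------------------
  if ("permanova" %in% stages) stage("permanova", {
    for (kg in c("fungi", "bacteria")) {
      clr <- if (kg == "fungi") norm$clr_fungi else norm$clr_bacteria
      tab <- permanova_sequential(aitchison_distance(clr), ds$metadata,
                                  config$term_order, n_perm = config$n_perm,
                                  seed = config$seed + 30L)
      emit(tab, paste0("permanova_", kg, ".tsv"), "permanova_table")
    }
  })

  ## -- phylosymbiosis -----------------------------------------------------
  if ("phylosymbiosis" %in% stages) stage("phylosymbiosis", {
    res <- do.call(rbind, lapply(c("fungi", "bacteria"), function(kg) {
      sw <- suppressWarnings(phylosymbiosis_test(
        if (kg == "fungi") ds$fungi else ds$bacteria,
        if (kg == "fungi") ds$taxonomy_fungi else ds$taxonomy_bacteria,
        ds$metadata, ds$tree, rank_levels = config$rank_levels,
        n_boot = config$n_boot, frac = config$frac,
        seed = config$seed + 40L, pseudocount_rule = config$pseudocount_rule))
      sweep_to_df(sw, kg)
    }))
    emit(res, "phylosymbiosis.tsv", "bootstrap_sweep")
  })

  ## -- cross-kingdom Procrustes -------------------------------------------
  if ("procrustes" %in% stages) stage("procrustes", {
    sw <- bootstrap_procrustes(ds$fungi, ds$bacteria, ds$taxonomy_fungi,
                               ds$taxonomy_bacteria,
                               rank_levels = config$rank_levels,
                               frac = config$frac, n_boot = config$n_boot,
                               seed = config$seed + 50L,
                               pseudocount_rule = config$pseudocount_rule)
    emit(sweep_to_df(sw, "cross_kingdom"), "procrustes_ranks.tsv", "bootstrap_sweep")
    shared <- intersect(sample_ids(ds$fungi), sample_ids(ds$bacteria))
    pf <- pca(clr_transform(subset_samples(ds$fungi, shared),
                            config$pseudocount_rule))$scores
    pb <- pca(clr_transform(subset_samples(ds$bacteria, shared),
                            config$pseudocount_rule))$scores
    pt <- protest(pf, pb, n_perm = config$n_perm, seed = config$seed + 51L)
    emit(data.frame(correlation = pt$correlation, m12_squared = pt$m12_squared,
                    p = pt$p, n_perm = pt$n_perm, n_shared = pt$n_shared),
         "protest_asv.tsv", "protest")
  })

  ## -- diet ---------------------------------------------------------------
  if ("diet" %in% stages) stage("diet", {
    if (is.null(ds$diet)) {
      note("diet table absent; diet stage skipped")
    } else {
      da <- diet_analysis(ds$fungi, ds$bacteria, ds$metadata, ds$diet,
                          n_perm = config$n_perm, n_boot = config$n_boot,
                          seed = config$seed + 60L,
                          pseudocount_rule = config$pseudocount_rule)
      emit(data.frame(kingdom = c("fungi", "bacteria"),
                      mantel_r = c(da$mantel$fungi$r, da$mantel$bacteria$r),
                      mantel_p = c(da$mantel$fungi$p, da$mantel$bacteria$p)),
           "diet_mantel.tsv", "diet_mantel")
      emit(da$slopes, "diet_slopes.tsv", "diet_slopes")
      emit(data.frame(species = rownames(da$pca$scores), da$pca$scores,
                      check.names = FALSE),
           "diet_pca.tsv", "diet_pca")
    }
  })

  ## -- networks -----------------------------------------------------------
  if ("networks" %in% stages) stage("networks", {
    nets <- species_and_class_networks(
      ds$fungi, ds$bacteria, ds$taxonomy_fungi, ds$taxonomy_bacteria,
      ds$metadata, depth = config$depth, threshold = config$rho_threshold,
      min_prevalence = config$min_prevalence, min_samples = config$min_samples,
      seed = config$seed + 70L)
    for (lvl in c("species", "class")) {
      tr <- nets[[lvl]]$traits
      if (!is.null(tr)) emit(tr, paste0("network_traits_", lvl, ".tsv"),
                             "network_traits")
      if (length(nets[[lvl]]$skipped)) {
        note(sprintf("networks (%s) skipped groups: %s", lvl,
                     paste(nets[[lvl]]$skipped, collapse = ",")))
      }
    }
    ## null tests on each class-level network with cross-kingdom edges
    nulls <- do.call(rbind, lapply(nets$class$networks, function(net) {
      bt <- tryCatch(betweenness_null_test(net, n_perm = config$n_perm,
                                           seed = config$seed + 71L),
                     error = function(e) NULL)
      pp <- tryCatch({
        freq <- phylum_pair_frequency(net)
        top <- which(freq == max(freq), arr.ind = TRUE)[1, ]
        pair <- c(rownames(freq)[top[1]], colnames(freq)[top[2]])
        list(pair = pair,
             test = phylum_pair_null_test(net, pair, n_perm = config$n_perm,
                                          seed = config$seed + 72L))
      }, error = function(e) NULL)
      rbind(
        if (!is.null(bt)) data.frame(group = net$group, test = "fungal_betweenness",
                                     detail = "", observed = bt$observed, p = bt$p),
        if (!is.null(pp)) data.frame(group = net$group, test = "phylum_pair",
                                     detail = paste(pp$pair, collapse = "x"),
                                     observed = pp$test$observed, p = pp$test$p)
      )
    }))
    if (!is.null(nulls) && nrow(nulls)) emit(nulls, "network_nulls.tsv", "network_nulls")
  })

  manifest <- list(
    package = "phylosym",
    version = as.character(utils::packageVersion("phylosym")),
    config = config[setdiff(names(config), character(0))],
    stages = stages,
    outputs = lapply(stats::setNames(nm = basename(outputs)), function(b) {
      path <- file.path(outdir, b)
      p <- outputs[basename(outputs) == b][1]
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log("run complete: %d output files", length(outputs))
  invisible(manifest)
}

#' Render a markdown summary of a pipeline run
#'
#' @param outdir directory produced by [run_all()].
#' @param path output markdown path (default `report.md` inside
#'   `outdir`).
#' @return the report path, invisibly; regeneration is idempotent.
#' @export
report <- function(outdir, path = file.path(outdir, "report.md")) {
  manifest_path <- file.path(outdir, "manifest.json")
  if (!file.exists(manifest_path)) abort("no manifest.json in ", outdir)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c("# phylosym run report", "",
             sprintf("Package version %s.", manifest$version), "")
  read_out <- function(name) {
    p <- file.path(outdir, name)
    if (file.exists(p)) read_tsv_checked(p) else NULL
  }
  md_table <- function(df) {
    fmt <- function(x) if (is.numeric(x)) formatC(x, digits = 4, format = "g") else as.character(x)
    body <- apply(as.data.frame(lapply(df, fmt)), 1, paste, collapse = " | ")
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "), body, "")
  }
  section <- function(title, name) {
    df <- read_out(name)
    if (is.null(df)) c(paste("##", title), "", "_skipped_", "")
    else c(paste("##", title), "", md_table(df))
  }
  lines <- c(lines,
             section("Sequential PERMANOVA (fungi)", "permanova_fungi.tsv"),
             section("Sequential PERMANOVA (bacteria)", "permanova_bacteria.tsv"),
             section("Phylogenetic signal", "phylo_signal.tsv"),
             section("Paired richness", "paired_richness.tsv"),
             section("Phylosymbiosis correlation by rank", "phylosymbiosis.tsv"),
             section("Cross-kingdom Procrustes by rank", "procrustes_ranks.tsv"),
             section("PROTEST (ASV level)", "protest_asv.tsv"),
             section("Diet Mantel", "diet_mantel.tsv"),
             section("Diet slopes", "diet_slopes.tsv"),
             section("Network traits (class level)", "network_traits_class.tsv"),
             section("Network null tests", "network_nulls.tsv"))
  if (length(manifest$warnings)) {
    lines <- c(lines, "## Warnings", "", paste("-", unlist(manifest$warnings)), "")
  }
  writeLines(lines, path)
  invisible(path)
}
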