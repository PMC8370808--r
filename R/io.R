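## IO and validation for the five core data types.  Everything is plain
## TSV (UTF-8, '.' decimal, features in rows) except trees, which are
## Newick.  Writers emit a one-line schema comment; readers skip '#'.

SCHEMA_VERSION <- "phylosym-schema: v1"

TAXONOMY_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")
METADATA_COLS <- c("sample_id", "host_species", "host_order", "host_class",
                   "sample_type", "tissue_storage", "extraction_kit")
DIET_CATEGORIES <- c("invertebrates", "vert_endotherms", "vert_ectotherms",
                     "fish", "vert_unknown", "scavenge", "fruit", "nectar",
                     "seeds", "plants")

# ---------------------------------------------------------------------------
# FeatureTable

#' Construct a validated feature table
#'
#' A feature table is a non-negative integer count matrix with features
#' (ASVs or agglomerated taxa) in rows and samples in columns, tagged
#' with the microbial kingdom it describes.
#'
#' @param counts integer matrix, features x samples, with unique
#'   rownames (feature ids) and colnames (sample ids).
#' @param kingdom one of `"fungi"`, `"bacteria"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(counts, kingdom = c("fungi", "bacteria")) {
  kingdom <- match.arg(kingdom)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("feature table requires feature and sample ids as dimnames",
          class = "phylosym_validation_error")
  }
  dup_f <- unique(rownames(counts)[duplicated(rownames(counts))])
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_f)) {
    abort("duplicate feature id(s): ", paste(dup_f, collapse = ", "),
          class = "phylosym_validation_error")
  }
  if (length(dup_s)) {
    abort("duplicate sample id(s): ", paste(dup_s, collapse = ", "),
          class = "phylosym_validation_error")
  }
  if (any(!is.finite(counts))) {
    abort("counts must be finite", class = "phylosym_validation_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)[1, ]
    abort(sprintf("counts must be non-negative integers; offending cell row '%s', column '%s'",
                  rownames(counts)[bad[1]], colnames(counts)[bad[2]]),
          class = "phylosym_parse_error")
  }
  storage.mode(counts) <- "double"   # exact for counts < 2^53
  structure(list(counts = counts, kingdom = kingdom),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d features x %d samples, total reads %s\n",
              x$kingdom, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
feature_ids <- function(x) rownames(x$counts)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$counts)

#' Read a feature table from TSV
#'
#' Expects a header row of sample ids, a first column of feature ids,
#' and integer cells.  Lines starting with `#` are ignored.
#'
#' @param path path to a TSV file.
#' @param kingdom kingdom label to attach.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, kingdom = c("fungi", "bacteria")) {
  kingdom <- match.arg(kingdom)
  raw <- read_tsv_checked(path)
  if (ncol(raw) < 2L) abort("feature table needs at least one sample column",
                            class = "phylosym_parse_error")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(raw[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    loc <- if (length(bad)) sprintf(" (first at row %d, column %d)", bad[1], bad[2] + 1L) else ""
    abort("non-numeric cell in feature table", loc, class = "phylosym_parse_error")
  }
  rownames(mat) <- ids
  feature_table(mat, kingdom)
}

#' Write a feature table to TSV
#' @param x a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  stopifnot(inherits(x, "feature_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA_VERSION, " feature_table kingdom=", x$kingdom), con)
  df <- data.frame(feature_id = feature_ids(x),
                   x$counts, check.names = FALSE)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Shared TSV plumbing

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) abort("empty file: ", path, class = "phylosym_parse_error")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  dup <- unique(header[duplicated(header)])
  if (length(dup)) {
    abort("duplicate column id(s): ", paste(dup, collapse = ", "),
          class = "phylosym_validation_error")
  }
  utils::read.table(text = lines, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA, comment.char = "")
}

write_tsv_schema <- function(df, path, type) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA_VERSION, " ", type), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# HostTree

validate_host_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylo tree", class = "phylosym_format_error")
  if (is.null(tree$edge.length)) {
    abort("tree has no branch lengths", class = "phylosym_validation_error")
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0)) {
    abort("negative or non-finite branch length in tree",
          class = "phylosym_validation_error")
  }
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup)) {
    abort("duplicate tip label(s): ", paste(dup, collapse = ", "),
          class = "phylosym_validation_error")
  }
  tree
}

#' Read a host phylogeny from a Newick file
#'
#' The tree must be a single rooted tree with branch lengths (time
#' units) and unique tip labels; branch lengths must be non-negative.
#'
#' @param path path to a Newick file.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) abort("cannot parse Newick: ", conditionMessage(e),
                                             class = "phylosym_format_error"))
  if (is.null(tree)) abort("cannot parse Newick file ", path, class = "phylosym_format_error")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_host_tree(tree)
}

#' Write a host phylogeny to a Newick file
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  validate_host_tree(tree)
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

# ---------------------------------------------------------------------------
# SampleMetadata

#' Read sample metadata from TSV
#'
#' Requires exactly the columns `sample_id`, `host_species`,
#' `host_order`, `host_class`, `sample_type`, `tissue_storage`,
#' `extraction_kit`, one row per sample, no missing values.
#'
#' @param path path to a TSV file.
#' @return a `sample_metadata` data frame.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(path)
  sample_metadata(df)
}

#' @rdname read_metadata
#' @param df data frame with the documented metadata schema.
#' @export
sample_metadata <- function(df) {
  missing <- setdiff(METADATA_COLS, names(df))
  if (length(missing)) {
    abort("metadata missing required column(s): ", paste(missing, collapse = ", "),
          class = "phylosym_schema_error")
  }
  df <- df[, METADATA_COLS]
  for (col in METADATA_COLS) df[[col]] <- as.character(df[[col]])
  if (anyNA(df) || any(df == "")) {
    abort("metadata contains missing values", class = "phylosym_validation_error")
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) abort("duplicate sample id(s) in metadata: ",
                         paste(dup, collapse = ", "),
                         class = "phylosym_validation_error")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' @export
write_metadata <- function(df, path) write_tsv_schema(df, path, "sample_metadata")

# ---------------------------------------------------------------------------
# TaxonomyTable

#' Read a taxonomy table from TSV
#'
#' Requires columns `feature_id` plus the six ranks kingdom..genus.
#' Blank or missing ranks are normalized to the literal token
#' `"unassigned"` so downstream agglomeration has deterministic bins.
#'
#' @param path path to a TSV file.
#' @return a `taxonomy_table` data frame.
#' @export
read_taxonomy <- function(path) {
  taxonomy_table(read_tsv_checked(path))
}

#' @rdname read_taxonomy
#' @param df data frame with `feature_id` and rank columns.
#' @export
taxonomy_table <- function(df) {
  required <- c("feature_id", TAXONOMY_RANKS)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort("taxonomy missing required column(s): ", paste(missing, collapse = ", "),
          class = "phylosym_schema_error")
  }
  df <- df[, required]
  for (col in required) {
    v <- as.character(df[[col]])
    if (col != "feature_id") v[is.na(v) | v == ""] <- "unassigned"
    df[[col]] <- v
  }
  dup <- unique(df$feature_id[duplicated(df$feature_id)])
  if (length(dup)) abort("duplicate feature id(s) in taxonomy: ",
                         paste(dup, collapse = ", "),
                         class = "phylosym_validation_error")
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' @export
write_taxonomy <- function(df, path) write_tsv_schema(df, path, "taxonomy_table")

# ---------------------------------------------------------------------------
# DietTable

#' Read a per-species diet-proportion table from TSV
#'
#' Requires a `species` column plus ten diet-category columns (in the
#' style of EltonTraits semi-quantitative diets), each in \[0, 100\];
#' every row must sum to 100 within 0.5.
#'
#' @param path path to a TSV file.
#' @return a `diet_table` data frame.
#' @export
read_diet <- function(path) diet_table(read_tsv_checked(path))

#' @rdname read_diet
#' @param df data frame with `species` and the ten diet categories.
#' @export
diet_table <- function(df) {
  required <- c("species", DIET_CATEGORIES)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort("diet table missing required column(s): ", paste(missing, collapse = ", "),
          class = "phylosym_schema_error")
  }
  df <- df[, required]
  df$species <- as.character(df$species)
  prop <- as.matrix(df[, DIET_CATEGORIES])
  if (any(!is.finite(prop)) || any(prop < 0) || any(prop > 100)) {
    abort("diet proportions must lie in [0, 100]", class = "phylosym_validation_error")
  }
  sums <- rowSums(prop)
  bad <- which(abs(sums - 100) > 0.5)
  if (length(bad)) {
    abort(sprintf("diet proportions for species '%s' sum to %.3f, expected 100 +- 0.5",
                  df$species[bad[1]], sums[bad[1]]),
          class = "phylosym_validation_error")
  }
  dup <- unique(df$species[duplicated(df$species)])
  if (length(dup)) abort("duplicate species in diet table: ",
                         paste(dup, collapse = ", "),
                         class = "phylosym_validation_error")
  class(df) <- c("diet_table", "data.frame")
  df
}

#' @export
write_diet <- function(df, path) write_tsv_schema(df, path, "diet_table")

# ---------------------------------------------------------------------------
# Cross-object validation

#' Check that a feature table aligns with metadata and taxonomy
#'
#' Samples present in the table but absent from the metadata (and
#' features absent from the taxonomy) are an error, not a silent drop;
#' the error reports the set differences.  Use [subset_samples()] for
#' intentional filtering.
#'
#' @param table a `feature_table`.
#' @param metadata a `sample_metadata` (optional).
#' @param taxonomy a `taxonomy_table` (optional).
#' @return `TRUE`, invisibly, if everything aligns.
#' @export
validate_alignment <- function(table, metadata = NULL, taxonomy = NULL) {
  if (!is.null(metadata)) {
    extra <- setdiff(sample_ids(table), metadata$sample_id)
    if (length(extra)) {
      abort("samples missing from metadata: ", paste(extra, collapse = ", "),
            class = "phylosym_validation_error")
    }
  }
  if (!is.null(taxonomy)) {
    extra <- setdiff(feature_ids(table), taxonomy$feature_id)
    if (length(extra)) {
      abort("features missing from taxonomy: ", paste(extra, collapse = ", "),
            class = "phylosym_validation_error")
    }
  }
  invisible(TRUE)
}

#' Subset a feature table to a set of samples
#' @param table a `feature_table`.
#' @param keep character vector of sample ids to keep (order preserved).
#' @return a `feature_table`.
#' @export
subset_samples <- function(table, keep) {
  missing <- setdiff(keep, sample_ids(table))
  if (length(missing)) abort("unknown sample id(s): ", paste(missing, collapse = ", "))
  feature_table(table$counts[, keep, drop = FALSE], table$kingdom)
}
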