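#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(..., class = "phylosym_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s", name, min),
          class = "phylosym_argument_error")
  }
  as.integer(x)
}

check_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max),
          class = "phylosym_argument_error")
  }
  as.numeric(x)
}

## Permutation p-value, (b + 1) / (n_perm + 1) convention so p = 0 is
## impossible regardless of the number of permutations.
perm_pvalue <- function(null, observed, tail = c("upper", "lower", "two_sided")) {
  tail <- match.arg(tail)
  b <- switch(tail,
    upper     = sum(null >= observed),
    lower     = sum(null <= observed),
    two_sided = sum(abs(null) >= abs(observed))
  )
  (b + 1) / (length(null) + 1)
}

## Symmetric distance objects are stored as plain labelled matrices.
as_distance_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  if (is.null(rownames(m))) abort("distance matrix must carry labels")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("distance matrix must be symmetric")
  }
  diag(m) <- 0
  class(m) <- c("distance_matrix", class(m))
  m
}

upper_tri_vec <- function(m) m[upper.tri(m)]
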