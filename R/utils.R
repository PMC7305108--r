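# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# `seed = NULL` means: use (and advance) the current RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1009 + offset) %% .Machine$integer.max
}

stop_if_not_scalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (anyNA(x))
    stop(sprintf("`%s` contains missing values", name), call. = FALSE)
  invisible(x)
}

# Canonical unordered-pair keys ("a||b" with a < b) used to intersect pair
# sets across detection runs and against ground truth.
pair_keys <- function(gene_i, gene_j) {
  a <- pmin(as.character(gene_i), as.character(gene_j))
  b <- pmax(as.character(gene_i), as.character(gene_j))
  paste(a, b, sep = "||")
}
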