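#' Gene-set collection restricted to a universe
#'
#' @param sets Named list of character vectors of gene ids.
#' @param universe Character vector: the genes under study (typically the
#'   genes scored in the run, not the genome). Sets are intersected with it.
#' @param drop_empty Drop sets with no gene in the universe (default TRUE).
#' @return Object of class `gene_set_collection`: list with `sets`
#'   (restricted), `universe`.
#' @export
gene_set_collection <- function(sets, universe, drop_empty = TRUE) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names", call. = FALSE)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)),
                                             universe))
  if (drop_empty) sets <- sets[lengths(sets) > 0]
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene1<TAB>...`.
#' Parsing is delegated to [fgsea::gmtPathways()].
#'
#' @param path Path to a `.gmt` file.
#' @param universe Optional universe to restrict to (see
#'   [gene_set_collection()]); if `NULL`, the union of all set genes is used.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' Fold-enrichment pathway score of a module
#'
#' `pathway_score = n / m` where `n` is the fraction of the module occupied
#' by pathway genes (`|module ∩ set| / |module|`) and `m` is the fraction of
#' the universe occupied by pathway genes (`|set ∩ universe| / |universe|`):
#' a fold-enrichment of the pathway in the module over its background rate.
#' A value of 1 means no enrichment. The alternative reading of `n` as the
#' fraction of the *pathway* captured (`|module ∩ set| / |set ∩ universe|`)
#' is available via `mode = "set_fraction"`.
#'
#' @param module_genes,set_genes Character vectors of gene ids.
#' @param universe Character vector of background genes.
#' @param mode `"module_fraction"` (default) or `"set_fraction"`.
#' @return Scalar score >= 0.
#' @examples
#' pathway_score(paste0("g", 1:10), paste0("g", c(1:5, 90:104)),
#'               paste0("g", 1:100))  # (5/10) / (20/100) = 2.5
#' @export
pathway_score <- function(module_genes, set_genes, universe,
                          mode = c("module_fraction", "set_fraction")) {
  mode <- match.arg(mode)
  universe <- unique(as.character(universe))
  module_genes <- intersect(unique(as.character(module_genes)), universe)
  set_in_u <- intersect(unique(as.character(set_genes)), universe)
  if (length(module_genes) == 0) stop("module empty in universe",
                                      call. = FALSE)
  if (length(set_in_u) == 0) stop("set absent from universe", call. = FALSE)
  ov <- length(intersect(module_genes, set_in_u))
  n <- if (mode == "module_fraction") ov / length(module_genes)
       else ov / length(set_in_u)
  m <- length(set_in_u) / length(universe)
  n / m
}

#' Hypergeometric over-representation of gene sets in modules
#'
#' For every (module, set) combination, the upper-tail hypergeometric
#' p-value `P(X >= overlap)` with the module as the draw and the set as the
#' successes in the universe, Benjamini-Hochberg corrected across all tests
#' performed. The fold-enrichment [pathway_score()] is reported alongside.
#'
#' @param modules A `module_set` from [detect_modules()], or a named list of
#'   character vectors (module id -> genes).
#' @param sets A [gene_set_collection()].
#' @param alpha FDR significance level (default 0.05).
#' @return `data.frame` with one row per (module, set): `module_id`,
#'   `set_name`, `overlap_count`, `module_size`, `set_size_in_universe`,
#'   `universe_size`, `pathway_score`, `p_value`, `fdr`, `significant`.
#' @export
hypergeom_enrich <- function(modules, sets, alpha = 0.05) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  mod_list <- if (inherits(modules, "module_set")) {
    split(modules$genes, modules$labels)
  } else modules
  universe <- sets$universe
  U <- length(universe)
  rows <- list()
  for (mid in names(mod_list)) {
    mg <- intersect(mod_list[[mid]], universe)
    if (length(mg) == 0) next
    for (sn in names(sets$sets)) {
      sg <- sets$sets[[sn]]
      ov <- length(intersect(mg, sg))
      p <- phyper(ov - 1, length(sg), U - length(sg), length(mg),
                  lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = mid, set_name = sn, overlap_count = ov,
        module_size = length(mg), set_size_in_universe = length(sg),
        universe_size = U,
        pathway_score = pathway_score(mg, sg, universe),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no testable (module, set) combination",
                              call. = FALSE)
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$fdr <= alpha
  rownames(out) <- NULL
  out
}

#' CCDF of per-module best pathway scores
#'
#' For each threshold t, the fraction of modules whose *best* pathway score
#' is at least t: how often modules clear a given enrichment level. A
#' non-increasing step curve in \[0, 1\].
#'
#' @param results `data.frame` from [hypergeom_enrich()] (needs `module_id`
#'   and `pathway_score`).
#' @param thresholds Numeric vector of thresholds; default: 101 points from
#'   0 to the maximum observed score.
#' @return `data.frame` with columns `threshold`, `fraction`.
#' @export
ccdf_pathway_scores <- function(results, thresholds = NULL) {
  if (nrow(results) == 0) stop("results is empty", call. = FALSE)
  best <- tapply(results$pathway_score, results$module_id, max)
  if (is.null(thresholds))
    thresholds <- seq(0, max(best), length.out = 101)
  data.frame(threshold = thresholds,
             fraction = vapply(thresholds,
                               function(t) mean(best >= t), numeric(1)))
}
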