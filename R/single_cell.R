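#' Within-CAG co-occurrence count in single cells
#'
#' Counts (cell, gene) detections for which at least one other gene of the
#' same CAG is detected in the same cell. The unit is the detection, so a
#' gene seen in two cells can contribute twice. Genes absent from the
#' catalog are dropped first; the number dropped is attached as attribute
#' `n_unknown_detections`.
#'
#' @param cells data.frame with columns `cell`, `gene` (one row per
#'   detection; duplicates are collapsed).
#' @param catalog A [cag_catalog()].
#' @return Integer count with attribute `n_unknown_detections`.
#' @export
cooccurrence_count <- function(cells, catalog) {
  stopifnot(is_cag_catalog(catalog))
  if (!nrow(cells)) stop("empty cell-gene table", call. = FALSE)
  cells <- unique(cells[, c("cell", "gene")])
  known <- cells$gene %in% names(catalog$gene)
  n_unknown <- sum(!known)
  cells <- cells[known, , drop = FALSE]
  if (!nrow(cells))
    stop("no detections remain after dropping genes absent from the catalog",
         call. = FALSE)
  cnt <- count_with_labels(cells$cell, catalog$gene[cells$gene])
  structure(cnt, n_unknown_detections = n_unknown)
}

# detections whose (cell, CAG) pair occurs at least twice
count_with_labels <- function(cell, cag) {
  key <- paste(cell, cag, sep = "\r")
  idx <- match(key, key)            # first occurrence index per key
  sum(tabulate(idx)[idx] >= 2L)
}

#' Permutation test for within-CAG co-occurrence
#'
#' Compares the observed co-occurrence count to its null distribution
#' under random permutation of the gene-to-CAG assignment over the
#' catalog's gene universe (the multiset of CAG sizes is preserved
#' exactly). The enrichment ratio is the observed count divided by the
#' mean permuted count.
#'
#' @param cells data.frame with columns `cell`, `gene`.
#' @param catalog A [cag_catalog()].
#' @param n_reps Number of permutation replicates (default 1000).
#' @param seed Integer seed.
#' @return List: `observed`, `perm_mean`, `perm_sd`, `ratio`,
#'   `rank` (of observed among observed + null draws), `n_reps`, `seed`,
#'   `defined` (`FALSE` when the permutation mean is zero).
#' @export
permutation_ratio <- function(cells, catalog, n_reps = 1000, seed = 1L) {
  stopifnot(n_reps >= 1)
  obs <- cooccurrence_count(cells, catalog)
  cells <- unique(cells[, c("cell", "gene")])
  cells <- cells[cells$gene %in% names(catalog$gene), , drop = FALSE]
  universe <- names(catalog$gene)
  labels <- unname(catalog$gene[universe])
  gene_idx <- match(cells$gene, universe)
  set.seed(seed)
  perm <- vapply(seq_len(n_reps), function(r) {
    shuffled <- labels[sample.int(length(labels))]
    count_with_labels(cells$cell, shuffled[gene_idx])
  }, 0L)
  mu <- mean(perm)
  list(observed = as.integer(obs),
       perm_mean = mu, perm_sd = stats::sd(perm),
       ratio = if (mu > 0) as.integer(obs) / mu else NA_real_,
       rank = sum(perm < obs) + 1L,
       n_reps = as.integer(n_reps), seed = as.integer(seed),
       defined = mu > 0,
       n_unknown_detections = attr(obs, "n_unknown_detections"))
}
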