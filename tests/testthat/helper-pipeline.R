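# shared helpers: small deterministic fixtures and the two association
# pipelines (CAG-level and representative-gene-level)

toy_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 3 else length(genes))
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  abundance_matrix(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_cag_pipeline <- function(coh, catalog, model = "auto") {
  ca <- cag_abundance(sum_normalize(coh$abundance), catalog)
  suppressWarnings(
    fit_cag_association(clr_transform(ca), coh$metadata, model = model))
}

fit_gene_pipeline <- function(coh, genes, model = "auto") {
  gm <- unclass(sum_normalize(coh$abundance))[genes, , drop = FALSE]
  fit_cag_association(clr_transform(gm), coh$metadata, model = model)
}

validation_rate <- function(rd, rv) {
  d <- discover(rd)
  if (!length(d)) return(NA_real_)
  suppressWarnings(validate_cags(d, rd, rv))$validation_rate
}

# a catalog of many small CAGs, as in real gene catalogs; used by the
# single-cell tests so the permutation null is not saturated
small_cag_catalog <- function(n_cags = 200, size = 3) {
  cag_catalog(stats::setNames(rep(seq_len(n_cags), each = size),
                              sprintf("g%04d", seq_len(n_cags * size))))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
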