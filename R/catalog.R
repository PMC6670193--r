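#' Construct a CAG catalog
#'
#' A catalog is a partition of genes into Co-Abundant Gene groups. CAG ids
#' are dense integers starting at 0, assigned in order of decreasing CAG
#' size with ties broken by the lexicographically smallest member gene id,
#' so the labeling is deterministic and invariant to input ordering.
#'
#' @param membership Named vector (names = gene ids) giving an arbitrary
#'   cluster label per gene; labels are re-coded to the canonical scheme.
#' @return A `cag_catalog` with elements `gene` (named integer vector,
#'   gene -> CAG id), `members` (list of member gene ids per CAG, indexed
#'   `as.character(cag_id)`), and `sizes` (named integer vector).
#' @export
cag_catalog <- function(membership) {
  if (length(membership) == 0)
    stop("empty membership", call. = FALSE)
  genes <- names(membership)
  if (is.null(genes) || anyNA(genes) || anyDuplicated(genes))
    stop("membership must be named by unique gene ids", call. = FALSE)
  raw <- split(genes, as.character(membership))
  # canonical order: descending size, ties by smallest member id
  minmem <- vapply(raw, function(g) min(g), "")
  ord <- order(-lengths(raw), minmem)
  members <- lapply(raw[ord], function(g) sort(g))
  names(members) <- as.character(seq_along(members) - 1L)
  gene <- rep.int(seq_along(members) - 1L, lengths(members))
  names(gene) <- unlist(members, use.names = FALSE)
  gene <- gene[order(names(gene))]
  structure(list(gene = gene, members = members,
                 sizes = stats::setNames(lengths(members), names(members))),
            class = "cag_catalog")
}

#' @export
print.cag_catalog <- function(x, ...) {
  cat(sprintf("<cag_catalog> %d genes in %d CAGs (sizes %d-%d)\n",
              length(x$gene), length(x$members),
              min(x$sizes), max(x$sizes)))
  invisible(x)
}

#' @rdname cag_catalog
#' @param x Object to test.
#' @export
is_cag_catalog <- function(x) inherits(x, "cag_catalog")

#' Summarize CAG sizes
#'
#' Tabulates the CAG size distribution, reporting singleton clusters
#' separately so either convention (keep or drop single-gene CAGs) can be
#' read off.
#'
#' @param catalog A [cag_catalog()].
#' @return A data.frame with one row per CAG size and its frequency, plus
#'   attributes `n_singletons` and `n_cags`.
#' @export
cag_size_summary <- function(catalog) {
  tab <- table(catalog$sizes)
  out <- data.frame(size = as.integer(names(tab)),
                    n_cags = as.integer(tab))
  attr(out, "n_singletons") <- sum(catalog$sizes == 1L)
  attr(out, "n_cags") <- length(catalog$sizes)
  out
}
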