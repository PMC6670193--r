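#' Construct a gene abundance matrix
#'
#' Wraps a numeric matrix of per-gene sequencing depth (genes as rows,
#' samples as columns) and tracks whether columns have been sum-normalized
#' to relative abundance.
#'
#' @param values Numeric matrix, genes x samples, non-negative. Must have
#'   unique, non-empty rownames (gene ids) and colnames (sample ids).
#' @param normalized Logical; `TRUE` if each sample column sums to 1.
#' @return An `abund_matrix`: the matrix with a `normalized` attribute.
#' @export
abundance_matrix <- function(values, normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("abundance matrix requires gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyNA(values) || any(values < 0)) {
    bad <- which(is.na(values) | values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative or missing abundance at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]),
         call. = FALSE)
  }
  if (normalized) {
    cs <- colSums(values)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off))
      stop("flagged normalized but column sums differ from 1 for sample(s): ",
           paste(colnames(values)[utils::head(off, 3)], collapse = ", "),
           call. = FALSE)
  }
  structure(values, normalized = normalized,
            class = c("abund_matrix", class(values)))
}

#' @export
print.abund_matrix <- function(x, ...) {
  cat(sprintf("<abund_matrix> %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "normalized"))) "relative abundance"
              else "raw depth"))
  invisible(x)
}

is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' Sum-normalize sample columns to relative abundance
#'
#' Divides each sample column by its total depth so columns sum to 1
#' ("sum" normalization). Idempotent on already-normalized input.
#'
#' @param m An [abundance_matrix()].
#' @return A normalized `abund_matrix`.
#' @export
sum_normalize <- function(m) {
  cs <- colSums(m)
  zero <- which(cs == 0)
  if (length(zero))
    stop("zero total depth in sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  abundance_matrix(sweep(unclass(m), 2, cs, "/"), normalized = TRUE)
}

#' Drop genes detected in too few samples
#'
#' A gene is detected in a sample when its abundance is strictly positive.
#' Detection is scale-invariant, so the filter gives identical results on
#' raw depth and on sum-normalized values.
#'
#' @param m An [abundance_matrix()].
#' @param min_samples Minimum number of samples a gene must be detected in.
#' @return List with `matrix` (retained genes, same normalization flag) and
#'   `excluded` (character vector of dropped gene ids).
#' @export
filter_min_samples <- function(m, min_samples = 10) {
  stopifnot(min_samples >= 1)
  det <- rowSums(unclass(m) > 0)
  keep <- det >= min_samples
  kept <- unclass(m)[keep, , drop = FALSE]
  # the normalized flag only survives if nothing was dropped: after removal
  # the retained columns no longer sum to 1
  still_norm <- is_normalized(m) && all(keep)
  list(matrix = structure(kept, normalized = still_norm,
                          class = c("abund_matrix", "matrix", "array")),
       excluded = rownames(m)[!keep])
}
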