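#' Clustering parameters
#'
#' Bundles the tunable parameters of CAG clustering. The defaults are the
#' published pipeline settings: a cophenetic cosine-distance threshold of
#' 0.3, a detection floor of 10 samples, and sum normalization (applied
#' inside [find_cags()]).
#'
#' @param max_dist Cophenetic cosine-distance threshold at which the
#'   average-linkage dendrogram is cut (inclusive). In (0, 1].
#' @param min_samples Minimum samples a gene must be detected in.
#' @param ann_k Approximate neighbors retrieved per query. When
#'   `ann_k >= n - 1` the neighbor search is performed exhaustively (the
#'   exact limit of the ANN contract).
#' @param ann_M HNSW graph degree.
#' @param ann_ef HNSW construction/search breadth.
#' @param max_rounds Cap on clustering rounds.
#' @param seed Integer seed recorded with the run. The clustering itself is
#'   deterministic given the input ordering; the seed is kept for interface
#'   stability and run logs.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(max_dist = 0.3, min_samples = 10,
                              ann_k = 100, ann_M = 16, ann_ef = 200,
                              max_rounds = 5, seed = 1L) {
  stopifnot(max_dist > 0, max_dist <= 1, min_samples >= 1, ann_k >= 2,
            ann_M >= 2, ann_ef >= 2, max_rounds >= 1)
  structure(list(max_dist = max_dist, min_samples = min_samples,
                 ann_k = as.integer(ann_k), ann_M = as.integer(ann_M),
                 ann_ef = as.integer(ann_ef),
                 max_rounds = as.integer(max_rounds),
                 seed = as.integer(seed)),
            class = "clustering_params")
}

#' Cosine distance between two abundance profiles
#'
#' `1 - u.v / (|u||v|)`; lies in `[0, 1]` for non-negative profiles and is
#' invariant to rescaling either vector, so per-gene profiles give the same
#' distances whether taken from raw depth or sum-normalized values.
#'
#' @param u,v Numeric vectors of equal length; neither may be all zero.
#' @return Cosine distance (scalar).
#' @export
cosine_distance <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine distance undefined for an all-zero profile", call. = FALSE)
  max(0, 1 - sum(u * v) / (nu * nv))
}

# rows scaled to unit L2 norm; errors on all-zero rows
unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("all-zero abundance profile for gene(s): ",
         paste(utils::head(rownames(m)[zero], 3), collapse = ", "),
         call. = FALSE)
  m / nrm
}

#' All-pairs cosine distance matrix over gene rows
#'
#' @param m Numeric matrix, profiles as rows.
#' @return A symmetric matrix of cosine distances, clamped to `[0, 2]`.
#' @export
cosine_distance_matrix <- function(m) {
  u <- unit_rows(unclass(m))
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

#' Exact average-linkage clustering at a cophenetic threshold
#'
#' The brute-force reference: full UPGMA on the all-pairs cosine distance
#' matrix, cut at cophenetic height `max_dist` (inclusive). Quadratic in
#' the number of genes, so capped; intended for verification and for small
#' problems.
#'
#' @param m Abundance matrix (genes x samples); raw or normalized (per-gene
#'   cosine is scale-invariant).
#' @param max_dist Cophenetic cut height.
#' @param max_genes Size guard for the all-pairs computation.
#' @return A [cag_catalog()].
#' @export
exact_average_linkage <- function(m, max_dist = 0.3, max_genes = 5000) {
  if (nrow(m) > max_genes)
    stop(sprintf("%d genes exceeds the all-pairs limit (%d); use find_cags()",
                 nrow(m), max_genes), call. = FALSE)
  if (nrow(m) == 1L)
    return(cag_catalog(stats::setNames(1L, rownames(m))))
  d <- cosine_distance_matrix(m)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, h = max_dist)
  cag_catalog(stats::setNames(cl, rownames(m)))
}

# --- candidate search -------------------------------------------------------

# connected components from an edge list over 1..n; returns component id per
# node (union-find with path halving)
edge_components <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ra <- find(from[e])
    rb <- find(to[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# k-nearest-neighbor pairs under cosine distance over the rows of `reps`.
# Exhaustive when k >= n - 1, otherwise HNSW. Returns a 2-column index
# matrix (i < j) of unique candidate pairs together with the distance
# implied by the representatives (callers re-verify with the exact
# cluster-level distance).
candidate_pairs <- function(reps, k, M = 16, ef = 200) {
  n <- nrow(reps)
  if (n < 2L) return(cbind(integer(0), integer(0)))
  u <- unit_rows(reps)
  if (k >= n - 1L) {
    sim <- tcrossprod(u)
    idx <- which(upper.tri(sim), arr.ind = TRUE)
    return(unname(idx))
  }
  k_q <- min(k + 1L, n)   # +1: the query itself is returned
  nn <- RcppHNSW::hnsw_knn(u, k = k_q, distance = "cosine",
                           M = M, ef_construction = max(ef, k_q),
                           ef = max(ef, k_q))
  i <- rep.int(seq_len(n), k_q)
  j <- as.vector(nn$idx)
  keep <- i != j
  a <- pmin(i[keep], j[keep]); b <- pmax(i[keep], j[keep])
  unique(cbind(a, b))
}

#' ANN candidate subsets of potentially co-abundant genes
#'
#' For each gene, retrieves approximate nearest neighbors under cosine
#' distance, verifies every candidate pair with the exact distance, keeps
#' pairs at or below `max_dist`, and returns the connected components of
#' the resulting graph. Every gene lands in exactly one subset (singletons
#' included), so components can be clustered independently of the whole.
#'
#' @param m Abundance matrix (genes x samples), normalized and filtered.
#' @param params A [clustering_params()].
#' @return Named list of character vectors of gene ids (one per subset).
#' @export
ann_candidate_groups <- function(m, params = clustering_params()) {
  u <- unit_rows(unclass(m))
  pr <- candidate_pairs(u, params$ann_k, params$ann_M, params$ann_ef)
  if (nrow(pr)) {
    d <- 1 - rowSums(u[pr[, 1], , drop = FALSE] * u[pr[, 2], , drop = FALSE])
    pr <- pr[d <= params$max_dist, , drop = FALSE]
  }
  comp <- edge_components(nrow(u), pr[, 1], pr[, 2])
  split(rownames(m), comp)
}

#' Find Co-Abundant Gene groups
#'
#' The main clustering entry point. Genes detected in at least
#' `min_samples` samples are sum-normalized and grouped by iterated,
#' ANN-accelerated average-linkage clustering: each round builds candidate
#' subsets from approximate nearest neighbors of the current clusters
#' (round 1: single genes), runs exact UPGMA within each subset with
#' inter-cluster distance equal to the mean over all member-pair cosine
#' distances, cuts at `max_dist`, and repeats until a round produces no
#' merges. Mean member-pair distances are computed exactly at any cluster
#' size via sums of unit member profiles, so the within-subset clustering
#' is true UPGMA on the underlying genes.
#'
#' @param m Abundance matrix (genes x samples), raw depth or normalized.
#' @param params A [clustering_params()].
#' @return A [cag_catalog()] over the retained genes, with attributes
#'   `excluded` (gene ids dropped by the detection filter) and `rounds`
#'   (number of clustering rounds run).
#' @export
find_cags <- function(m, params = clustering_params()) {
  flt <- filter_min_samples(m, params$min_samples)
  if (nrow(flt$matrix) == 0L)
    stop("no genes remain after the min_samples filter", call. = FALSE)
  mn <- sum_normalize(flt$matrix)
  u <- unit_rows(unclass(mn))          # fixed unit gene profiles
  n <- nrow(u)
  part <- seq_len(n)
  rounds <- 0L
  while (rounds < params$max_rounds) {
    rounds <- rounds + 1L
    part <- match(part, sort(unique(part)))   # dense labels 1..K
    S <- rowsum(u, part)                      # per-cluster sums of unit vectors
    sizes <- tabulate(part)
    if (nrow(S) == 1L) break
    pr <- candidate_pairs(S, params$ann_k, params$ann_M, params$ann_ef)
    merged <- FALSE
    if (nrow(pr)) {
      # exact mean member-pair cosine distance between clusters A and B:
      # 1 - (S_A . S_B) / (|A| |B|)
      dot <- rowSums(S[pr[, 1], , drop = FALSE] * S[pr[, 2], , drop = FALSE])
      d <- 1 - dot / (sizes[pr[, 1]] * sizes[pr[, 2]])
      pr <- pr[d <= params$max_dist, , drop = FALSE]
    }
    if (nrow(pr)) {
      comp <- edge_components(nrow(S), pr[, 1], pr[, 2])
      newlab <- seq_len(nrow(S))
      offset <- nrow(S)
      for (cid in unique(comp)) {
        idx <- which(comp == cid)
        if (length(idx) < 2L) next
        D <- 1 - tcrossprod(S[idx, , drop = FALSE]) /
          tcrossprod(matrix(sizes[idx], ncol = 1))
        D[D < 0] <- 0
        hc <- stats::hclust(stats::as.dist(D), method = "average",
                            members = sizes[idx])
        cl <- stats::cutree(hc, h = params$max_dist)
        newlab[idx] <- offset + cl
        offset <- offset + max(cl)
        if (max(cl) < length(idx)) merged <- TRUE
      }
      part <- newlab[part]
    }
    if (!merged) break
  }
  cat_out <- cag_catalog(stats::setNames(part, rownames(mn)))
  attr(cat_out, "excluded") <- flt$excluded
  attr(cat_out, "rounds") <- rounds
  cat_out
}

#' Aggregate gene abundance to CAG abundance
#'
#' Per CAG and sample, the sum of member genes' relative abundances.
#' Additive in depth units: a singleton CAG's row equals its gene's row and
#' column totals are conserved.
#'
#' @param m Sum-normalized abundance matrix covering the catalog's genes.
#' @param catalog A [cag_catalog()].
#' @return Matrix (CAGs x samples) with CAG ids as rownames.
#' @export
cag_abundance <- function(m, catalog) {
  if (!is_normalized(m))
    stop("`m` must be sum-normalized (see sum_normalize())", call. = FALSE)
  genes <- names(catalog$gene)
  missing <- setdiff(genes, rownames(m))
  if (length(missing))
    stop("catalog gene(s) absent from the abundance matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  agg <- rowsum(unclass(m)[genes, , drop = FALSE],
                group = catalog$gene[genes], reorder = TRUE)
  rownames(agg) <- as.character(sort(unique(catalog$gene[genes])))
  agg
}
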