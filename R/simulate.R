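#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. The generative model:
#' each CAG has a latent log relative-abundance level (normal across CAGs),
#' each sample draws a log-normal latent CAG abundance around that level,
#' disease shifts the log latent abundance of effect CAGs additively before
#' closure, subjects carry a random intercept shared by their repeated
#' samples, member genes scatter around their CAG's latent profile with
#' multiplicative log-normal noise, and sequencing draws Poisson counts at
#' the stated depth (so detection sparsity is realistic). Setting
#' `depth = Inf` skips count sampling and returns expected relative
#' abundances.
#'
#' @param n_cags Number of planted CAGs.
#' @param genes_per_cag Length-2 integer range; each CAG's size is drawn
#'   uniformly from it.
#' @param n_samples Samples per cohort.
#' @param n_subjects Subjects per cohort; subjects contribute 1-3 samples
#'   (every subject at least one), exercising the repeated-measures path.
#' @param effect_cags Number of CAGs with a non-zero disease effect.
#' @param effect_size Magnitude of the additive shift on natural-log latent
#'   abundance in healthy samples (sign drawn per effect CAG).
#' @param gene_noise_sd SD of per-gene, per-sample multiplicative
#'   log-normal noise around the CAG latent profile.
#' @param depth Expected total reads per sample (Poisson sampling), or
#'   `Inf` for noiseless expected abundances.
#' @param cag_level_sd SD of between-CAG log mean levels.
#' @param sample_sd SD of per-sample log-normal variation of latent CAG
#'   abundance (drives between-CAG cosine separation).
#' @param subject_sd SD of the subject-level random intercept on log
#'   abundance.
#' @param min_separation Minimum cosine distance between the latent
#'   (closure-adjusted) profiles of distinct CAGs; sample noise of an
#'   offending CAG is redrawn until the planted groups are co-abundance
#'   distinct, so the planted partition is well defined as the recoverable
#'   one.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cags = 20, genes_per_cag = c(10, 50),
                       n_samples = 60, n_subjects = 40,
                       effect_cags = 4, effect_size = 1,
                       gene_noise_sd = 0.1, depth = 1e5,
                       cag_level_sd = 1, sample_sd = 1.5,
                       subject_sd = 0.3, min_separation = 0.45, seed = 1L) {
  ok <- n_cags >= 1 && length(genes_per_cag) == 2 &&
    all(genes_per_cag >= 1) && genes_per_cag[1] <= genes_per_cag[2] &&
    n_samples >= 2 && n_subjects >= 2 && n_subjects <= n_samples &&
    effect_cags >= 0 && effect_cags <= n_cags && effect_size >= 0 &&
    gene_noise_sd >= 0 && depth > 0 && sample_sd > 0
  if (!ok) stop("invalid simulation configuration", call. = FALSE)
  structure(list(n_cags = as.integer(n_cags),
                 genes_per_cag = as.integer(genes_per_cag),
                 n_samples = as.integer(n_samples),
                 n_subjects = as.integer(n_subjects),
                 effect_cags = as.integer(effect_cags),
                 effect_size = effect_size, gene_noise_sd = gene_noise_sd,
                 depth = depth, cag_level_sd = cag_level_sd,
                 sample_sd = sample_sd, subject_sd = subject_sd,
                 min_separation = min_separation,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# shared structural truth: gene->CAG labels, CAG levels, gene levels,
# effect CAGs and their signs (healthy-positive convention)
draw_truth <- function(config) {
  sizes <- sample(seq(config$genes_per_cag[1], config$genes_per_cag[2]),
                  config$n_cags, replace = TRUE)
  n_genes <- sum(sizes)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  gene_cag <- rep.int(seq_len(config$n_cags), sizes)
  effect_idx <- if (config$effect_cags > 0)
    sort(sample(config$n_cags, config$effect_cags)) else integer(0)
  signs <- integer(config$n_cags)
  signs[effect_idx] <- sample(c(-1L, 1L), length(effect_idx), replace = TRUE)
  list(gene_ids = gene_ids, gene_cag = gene_cag, sizes = sizes,
       cag_mu = stats::rnorm(config$n_cags, 0, config$cag_level_sd),
       gene_level = stats::rlnorm(n_genes, 0, 1),
       effect_sign = signs)
}

# one cohort given structural truth; status/subject drawn here
draw_cohort <- function(config, truth, cohort_name) {
  ns <- config$n_samples
  # every subject gets one sample; remaining samples spread at random,
  # capped at 3 per subject
  subj_of <- seq_len(config$n_subjects)
  extra <- ns - config$n_subjects
  if (extra > 0) {
    pool <- rep(seq_len(config$n_subjects), 2L)   # at most 3 total
    subj_of <- c(subj_of, sample(pool, extra))
  }
  subj_of <- sort(subj_of)
  subj_status <- stats::rbinom(config$n_subjects, 1, 0.5)
  # guarantee both groups present
  if (all(subj_status == 0)) subj_status[1] <- 1L
  if (all(subj_status == 1)) subj_status[1] <- 0L
  status <- subj_status[subj_of]                  # 1 = disease
  healthy <- 1L - status
  b_subj <- stats::rnorm(config$n_subjects, 0, config$subject_sd)

  K <- config$n_cags
  # log latent CAG abundance per sample: level + sample noise + subject
  # intercept + healthy-side effect shift
  shift <- truth$effect_sign * config$effect_size
  base <- truth$cag_mu + matrix(rep(b_subj[subj_of], each = K), K, ns) +
    outer(shift, healthy)
  noise <- matrix(stats::rnorm(K * ns, 0, config$sample_sd), K, ns)
  # keep planted CAGs co-abundance distinct: redraw the sample noise of a
  # CAG whose closure-adjusted latent profile sits closer than
  # min_separation to another CAG's
  G <- as.vector(rowsum(truth$gene_level, truth$gene_cag))
  for (it in seq_len(200)) {
    lat <- exp(base + noise)
    if (K == 1L) break
    closed <- sweep(lat, 2, colSums(lat * G), "/")
    un <- closed / sqrt(rowSums(closed^2))
    d <- 1 - tcrossprod(un)
    close_pairs <- which(d < config$min_separation & upper.tri(d),
                         arr.ind = TRUE)
    if (!nrow(close_pairs)) break
    for (cc in unique(close_pairs[, 2]))
      noise[cc, ] <- stats::rnorm(ns, 0, config$sample_sd)
  }

  n_genes <- length(truth$gene_ids)
  noise <- if (config$gene_noise_sd > 0)
    matrix(stats::rlnorm(n_genes * ns, 0, config$gene_noise_sd), n_genes, ns)
  else 1
  x <- lat[truth$gene_cag, , drop = FALSE] * truth$gene_level * noise
  rel <- sweep(x, 2, colSums(x), "/")
  vals <- if (is.finite(config$depth)) {
    matrix(stats::rpois(length(rel), config$depth * rel), n_genes, ns)
  } else rel
  sample_ids <- sprintf("%s_s%03d", cohort_name, seq_len(ns))
  dimnames(vals) <- list(truth$gene_ids, sample_ids)
  meta <- data.frame(sample = sample_ids,
                     subject = sprintf("%s_subj%03d", cohort_name, subj_of),
                     status = status,
                     cohort = cohort_name,
                     stringsAsFactors = FALSE)
  list(abundance = abundance_matrix(vals,
                                    normalized = !is.finite(config$depth)),
       metadata = meta)
}

truth_set <- function(truth) {
  list(gene_cag = stats::setNames(truth$gene_cag, truth$gene_ids),
       effect_sign = stats::setNames(truth$effect_sign,
                                     seq_along(truth$effect_sign)),
       catalog = cag_catalog(stats::setNames(truth$gene_cag,
                                             truth$gene_ids)))
}

#' Simulate one cohort with planted CAG structure
#'
#' @param config A [sim_config()].
#' @return List with `abundance` (an [abundance_matrix()]), `metadata`
#'   (data.frame: sample, subject, status with 1 = disease, cohort), and
#'   `truth` (gene->CAG labels, per-CAG effect signs in the
#'   healthy-positive convention, and the planted [cag_catalog()]).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- draw_truth(config)
  coh <- draw_cohort(config, truth, "discovery")
  c(coh, list(truth = truth_set(truth)))
}

#' Simulate paired discovery and validation cohorts
#'
#' Both cohorts share the same planted CAG structure and effect signs but
#' have independent subjects and sampling noise, emulating the two-stage
#' discovery/validation design.
#'
#' @param config A [sim_config()].
#' @return List with `discovery` and `validation` (each `abundance` +
#'   `metadata`) and the shared `truth`.
#' @export
simulate_paired_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- draw_truth(config)
  disc <- draw_cohort(config, truth, "discovery")
  vali <- draw_cohort(config, truth, "validation")
  list(discovery = disc, validation = vali, truth = truth_set(truth))
}

#' Simulate a single-cell barcode-to-gene table
#'
#' Each cell detects `genes_per_cell` distinct genes. With
#' `within_cag_enrichment = 1` genes are sampled uniformly from the
#' catalog; larger values up-weight genes from a small number of "home"
#' CAGs chosen per cell, planting within-CAG co-occurrence.
#'
#' @param catalog A [cag_catalog()] giving the gene universe.
#' @param n_cells Number of cells.
#' @param genes_per_cell Genes detected per cell (sampled without
#'   replacement).
#' @param within_cag_enrichment Sampling weight multiplier (>= 1) for genes
#'   in the cell's home CAGs; 1 = uniform.
#' @param n_home_cags Home CAGs per cell.
#' @param seed Integer seed.
#' @return data.frame with columns `cell` and `gene`, one row per
#'   detection.
#' @export
simulate_single_cells <- function(catalog, n_cells, genes_per_cell,
                                  within_cag_enrichment = 1,
                                  n_home_cags = 2, seed = 1L) {
  stopifnot(is_cag_catalog(catalog), n_cells >= 0,
            within_cag_enrichment >= 1)
  genes <- names(catalog$gene)
  if (genes_per_cell > length(genes))
    stop("genes_per_cell exceeds the number of catalog genes", call. = FALSE)
  set.seed(seed)
  if (n_cells == 0)
    return(data.frame(cell = character(0), gene = character(0)))
  cags <- names(catalog$members)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    w <- rep(1, length(genes))
    if (within_cag_enrichment > 1) {
      home <- sample(cags, min(n_home_cags, length(cags)))
      w[catalog$gene[genes] %in% as.integer(home)] <- within_cag_enrichment
    }
    picked <- sample(genes, genes_per_cell, prob = w)
    rows[[i]] <- data.frame(cell = sprintf("cell_%05d", i), gene = picked,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
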