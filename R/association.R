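#' Centered log-ratio transform
#'
#' Per sample (column), the natural log of each abundance minus the mean
#' log across features, so the transformed values sum to zero within each
#' sample. Zeros are first replaced by a pseudocount: half the smallest
#' non-zero abundance in that sample (multiplicative replacement), keeping
#' geometric means finite without distorting non-zero parts.
#'
#' @param a Matrix (features x samples) of non-negative abundances with at
#'   least two rows.
#' @param zero_policy `"half-min"` (default) or `"error"` to refuse zeros.
#' @return Matrix of CLR values, same dimensions.
#' @export
clr_transform <- function(a, zero_policy = c("half-min", "error")) {
  zero_policy <- match.arg(zero_policy)
  a <- unclass(a)
  if (nrow(a) < 2) stop("CLR needs at least two features", call. = FALSE)
  allzero <- colSums(a) == 0
  if (any(allzero))
    stop("all-zero sample(s): ",
         paste(colnames(a)[allzero], collapse = ", "), call. = FALSE)
  if (any(a == 0)) {
    if (zero_policy == "error") stop("zero abundances present", call. = FALSE)
    for (j in which(colSums(a == 0) > 0)) {
      nz <- a[, j] > 0
      a[!nz, j] <- min(a[nz, j]) / 2
    }
  }
  lg <- log(a)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Per-CAG disease association models
#'
#' For each CAG, fits the CLR abundance against disease status. The status
#' predictor is coded 0 = disease, 1 = healthy, so a positive coefficient
#' means more abundant in health. When any subject contributes more than
#' one sample, a linear mixed model with a subject random intercept is
#' used (Wald z test against a normal reference); otherwise an ordinary
#' linear model (t test). Singular or failed fits yield `NA` p-values and
#' are excluded from q-value estimation.
#'
#' @param clr Matrix (CAGs x samples) of CLR abundances.
#' @param meta data.frame with columns `sample`, `subject`, `status`
#'   (1 = disease, 0 = healthy), one row per sample of `clr`.
#' @param model `"auto"` (default), `"fixed"`, or `"mixed"`.
#' @return data.frame with columns `cag`, `estimate`, `se`, `p`, `q`,
#'   `model`; q-values via [estimate_qvalues()].
#' @export
fit_cag_association <- function(clr, meta, model = c("auto", "fixed", "mixed")) {
  model <- match.arg(model)
  if (is.null(colnames(clr)))
    stop("clr matrix needs sample colnames", call. = FALSE)
  idx <- match(colnames(clr), meta$sample)
  if (anyNA(idx))
    stop("metadata missing for sample(s): ",
         paste(utils::head(colnames(clr)[is.na(idx)], 3), collapse = ", "),
         call. = FALSE)
  meta <- meta[idx, , drop = FALSE]
  if (anyNA(meta$status)) stop("missing disease status", call. = FALSE)
  healthy <- 1 - meta$status
  if (min(table(healthy)) < 2)
    stop("need at least 2 samples per disease-status group", call. = FALSE)
  repeated <- anyDuplicated(meta$subject) > 0
  use_mixed <- switch(model, auto = repeated, fixed = FALSE, mixed = TRUE)
  subject <- factor(meta$subject)

  fit_one <- function(y) {
    if (use_mixed) {
      tryCatch({
        fm <- suppressMessages(lme4::lmer(
          y ~ healthy + (1 | subject),
          control = lme4::lmerControl(
            check.conv.singular = "ignore",
            check.nobs.vs.nlev = "ignore",
            check.nobs.vs.rankZ = "ignore",
            check.nobs.vs.nRE = "ignore"),
          REML = TRUE))
        cf <- summary(fm)$coefficients
        est <- cf["healthy", "Estimate"]; se <- cf["healthy", "Std. Error"]
        c(est, se, 2 * stats::pnorm(-abs(est / se)))
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    } else {
      tryCatch({
        fm <- stats::lm(y ~ healthy)
        cf <- summary(fm)$coefficients
        if (!"healthy" %in% rownames(cf)) return(c(NA_real_, NA_real_, NA_real_))
        c(cf["healthy", "Estimate"], cf["healthy", "Std. Error"],
          cf["healthy", "Pr(>|t|)"])
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    }
  }
  res <- t(apply(clr, 1, fit_one))
  out <- data.frame(cag = rownames(clr),
                    estimate = res[, 1], se = res[, 2], p = res[, 3],
                    model = if (use_mixed) "mixed" else "fixed",
                    stringsAsFactors = FALSE, row.names = NULL)
  out$q <- as.vector(estimate_qvalues(out$p))
  out
}

#' Discovered CAGs at an FDR threshold
#'
#' @param results data.frame from [fit_cag_association()].
#' @param q_threshold Inclusive q-value cutoff (default 0.2, FDR 20%).
#' @return Character vector of discovered CAG ids.
#' @export
discover <- function(results, q_threshold = 0.2) {
  if (!nrow(results)) return(character(0))
  results$cag[!is.na(results$q) & results$q <= q_threshold]
}

#' Sign-matched validation of discovered CAGs
#'
#' Restricts the validation-cohort results to the discovered CAGs,
#' recomputes q-values within that subset only, and declares a CAG
#' validated when its validation q-value passes the threshold and its
#' coefficient has the same sign as in discovery. Also reports the
#' conservative global-null bound from sign agreement alone: among the C1
#' discovered CAGs tested, C2 retain their coefficient sign, and under the
#' global null C2 ~ Binomial(C1, 1/2).
#'
#' @param discovered Character vector of discovered CAG ids.
#' @param discovery_results,validation_results data.frames from
#'   [fit_cag_association()] on the two cohorts (same catalog).
#' @param q_threshold Inclusive q-value cutoff.
#' @return List: `validated` (CAG ids), `C1`, `C2`, `p_exact`,
#'   `p_normal_approx`, `log10_p_exact`, `validation_rate`, and the
#'   re-tested `results` subset.
#' @export
validate_cags <- function(discovered, discovery_results, validation_results,
                          q_threshold = 0.2) {
  if (!length(discovered))
    return(list(validated = character(0), C1 = 0L, C2 = 0L,
                p_exact = 1, p_normal_approx = 1,
                log10_p_exact = 0, validation_rate = NA_real_,
                results = validation_results[0, ]))
  missing <- setdiff(discovered, validation_results$cag)
  if (length(missing))
    stop("discovered CAG(s) missing from validation results: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  sub <- validation_results[validation_results$cag %in% discovered, ,
                            drop = FALSE]
  sub$q <- as.vector(estimate_qvalues(sub$p))
  dsign <- sign(discovery_results$estimate[
    match(sub$cag, discovery_results$cag)])
  agree <- !is.na(sub$estimate) & sign(sub$estimate) == dsign
  tested <- !is.na(sub$p)
  C1 <- sum(tested)
  C2 <- sum(agree & tested)
  validated <- sub$cag[tested & agree & !is.na(sub$q) & sub$q <= q_threshold]
  pv <- if (C1 >= 1) sign_agreement_pvalue(C1, C2)
        else list(exact = 1, normal_approx = 1, log10_exact = 0)
  list(validated = validated, C1 = C1, C2 = C2,
       p_exact = pv$exact, p_normal_approx = pv$normal_approx,
       log10_p_exact = pv$log10_exact,
       validation_rate = if (C1 >= 1) length(validated) / C1 else NA_real_,
       results = sub)
}

#' Conservative sign-agreement bound on the global null
#'
#' If C2 of C1 discovered features keep the same coefficient sign in an
#' independent validation cohort, then under the global null of no
#' association the sign matches are fair coin flips, so
#' `Pr(Binomial(C1, 0.5) >= C2)` bounds the p-value for observing at least
#' C2 matches. The exact tail is evaluated in log space (no underflow in
#' the log10 value even when the probability is below double precision).
#' The classical normal approximation with denominator `sqrt(C1/2)` is
#' returned alongside; it is more conservative than the binomial normal
#' approximation, whose standard deviation is `sqrt(C1)/2`.
#'
#' @param C1 Number of discovered features tested in validation.
#' @param C2 Number with the same coefficient sign in both cohorts.
#' @return List: `exact`, `log10_exact`, `normal_approx`,
#'   `log10_normal_approx`.
#' @export
sign_agreement_pvalue <- function(C1, C2) {
  stopifnot(length(C1) == 1, length(C2) == 1, C1 >= 1, C2 >= 0)
  if (C2 > C1) stop("C2 cannot exceed C1", call. = FALSE)
  lp <- stats::pbinom(C2 - 1, C1, 0.5, lower.tail = FALSE, log.p = TRUE)
  z <- (C2 - C1 / 2) / sqrt(C1 / 2)
  lpn <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  list(exact = exp(lp), log10_exact = lp / log(10),
       normal_approx = exp(lpn), log10_normal_approx = lpn / log(10))
}

#' Select one representative gene per CAG
#'
#' Uniform random member per CAG, deterministic given the seed; used to
#' rerun the association pipeline on unclustered gene-level abundances for
#' the clustered-vs-unclustered comparison.
#'
#' @param catalog A [cag_catalog()].
#' @param seed Integer seed.
#' @return Named character vector: CAG id -> gene id.
#' @export
select_representative_genes <- function(catalog, seed = 1L) {
  stopifnot(is_cag_catalog(catalog))
  set.seed(seed)
  vapply(catalog$members,
         function(g) if (length(g) == 1L) g else sample(g, 1L), "")
}

#' Fraction of CAGs with a positive coefficient
#'
#' @param results data.frame from [fit_cag_association()].
#' @return Fraction of tested (non-`NA`) CAGs with `estimate > 0`.
#' @export
sign_summary <- function(results) {
  est <- results$estimate[!is.na(results$estimate)]
  if (!length(est)) return(NA_real_)
  mean(est > 0)
}

#' Functional annotation enrichment by Fisher's exact test
#'
#' For each annotation label, builds the 2x2 table of membership in the
#' target gene set against presence of the label, computes the two-sided
#' Fisher exact p-value, and applies the Holm-Sidak step-down procedure at
#' family-wise alpha.
#'
#' @param target Character vector of gene ids (subset of `background`).
#' @param background Character vector of gene ids.
#' @param annotations data.frame with columns `gene`, `label` (a gene may
#'   have several rows or none).
#' @param alpha Family-wise error level for Holm-Sidak (default 0.01).
#' @return data.frame per label: counts, `odds_ratio`, `p`,
#'   `p_adjusted` (Holm-Sidak), `significant`; ordered by p.
#' @export
annotation_enrichment <- function(target, background, annotations,
                                  alpha = 0.01) {
  if (!all(target %in% background))
    stop("`target` must be a subset of `background`", call. = FALSE)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  dropped <- setdiff(unique(annotations$label), unique(ann$label))
  if (length(dropped))
    warning("label(s) absent from the background skipped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  labels <- sort(unique(ann$label))
  if (!length(labels))
    return(data.frame(label = character(0), in_target = integer(0),
                      in_background = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  tset <- unique(target)
  n_t <- length(tset); n_b <- length(unique(background))
  rows <- lapply(labels, function(lb) {
    lg <- unique(ann$gene[ann$label == lb])
    a <- length(intersect(lg, tset))          # target with label
    b <- n_t - a                              # target without
    cc <- length(lg) - a                      # non-target with label
    d <- (n_b - n_t) - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
    data.frame(label = lb, in_target = a, in_background = length(lg),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$label), , drop = FALSE]
  m <- nrow(out)
  # Holm-Sidak step-down: adjusted p_i = 1 - (1 - p_i)^(m - i + 1),
  # monotonized; reject while adjusted p <= alpha
  adj <- 1 - (1 - out$p)^(m - seq_len(m) + 1)
  out$p_adjusted <- pmin(1, cummax(adj))
  out$significant <- out$p_adjusted <= alpha
  rownames(out) <- NULL
  out
}
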