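test_that("CLR matches hand computation and sums to zero per sample", {
  a <- matrix(c(0.25, 0.25, 0.25, 0.25, 0.5, 0.25, 0.25, 0),
              nrow = 4, dimnames = list(sprintf("c%d", 1:4), c("s1", "s2")))
  a <- a[1:3, , drop = FALSE]
  a[, 2] <- c(0.5, 0.25, 0.25)
  clr <- clr_transform(a)
  expect_equal(unname(clr[, 1]), rep(0, 3))
  expect_equal(unname(clr[, 2]),
               log(c(0.5, 0.25, 0.25)) - mean(log(c(0.5, 0.25, 0.25))))
  expect_equal(unname(clr[1, 2]), 0.462, tolerance = 1e-3)
  set.seed(5)
  r <- matrix(rexp(60), 6, 10, dimnames = list(sprintf("c%d", 1:6),
                                               sprintf("s%d", 1:10)))
  r[r < 0.2] <- 0
  expect_lt(max(abs(colSums(clr_transform(r)))), 1e-9)
  expect_error(clr_transform(r, zero_policy = "error"), "zero")
  r[, 3] <- 0
  expect_error(clr_transform(r), "s3")
  expect_error(clr_transform(r[1, , drop = FALSE]), "two features")
})

test_that("zero-handling uses half the smallest non-zero value per sample", {
  a <- matrix(c(0.6, 0.4, 0, 0.5, 0.5, 0.1), 3,
              dimnames = list(c("c1", "c2", "c3"), c("s1", "s2")))
  clr <- clr_transform(a)
  imputed <- c(0.6, 0.4, 0.2)   # 0 -> min(0.6, 0.4)/2
  expect_equal(unname(clr[, 1]), log(imputed) - mean(log(imputed)))
})

test_that("association model recovers balance, reduction, and routing", {
  meta <- data.frame(sample = sprintf("s%d", 1:12),
                     subject = sprintf("u%d", 1:12),
                     status = rep(c(1, 0), each = 6))
  y <- rep(c(1, 2, 3), 4)   # same values in both groups
  clr <- rbind(c1 = y, c2 = y + rep(c(0, 1), each = 6))
  colnames(clr) <- meta$sample
  res <- suppressWarnings(fit_cag_association(clr, meta))
  expect_equal(res$model, c("fixed", "fixed"))
  expect_equal(res$estimate[1], 0, tolerance = 1e-12)
  expect_equal(res$p[1], 1, tolerance = 1e-9)
  expect_gt(res$estimate[2], 0)   # healthy-positive sign convention
  # forcing the mixed model with singleton subjects reproduces the fixed fit
  res_m <- suppressWarnings(fit_cag_association(clr, meta, model = "mixed"))
  expect_equal(res_m$estimate, res$estimate, tolerance = 1e-6)
  # automatic routing to the mixed model under repeated measures
  meta$subject <- rep(sprintf("u%d", 1:6), each = 2)
  res2 <- suppressWarnings(fit_cag_association(clr, meta))
  expect_equal(res2$model, c("mixed", "mixed"))
  expect_error(fit_cag_association(clr, meta[c(1, 2, 3), ]), "metadata")
  tiny <- data.frame(sample = colnames(clr)[1:3],
                     subject = c("a", "b", "c"), status = c(1, 0, 0))
  expect_error(fit_cag_association(clr[, 1:3], tiny), "2 samples per")
})

test_that("mixed and fixed estimates agree when subjects are unreplicated", {
  sim <- simulate_cohort(sim_config(n_cags = 10, genes_per_cag = c(2, 4),
                                    n_samples = 30, n_subjects = 30,
                                    seed = 22))
  rf <- fit_cag_pipeline(sim, sim$truth$catalog, model = "fixed")
  rm_ <- fit_cag_pipeline(sim, sim$truth$catalog, model = "mixed")
  expect_equal(rm_$estimate, rf$estimate, tolerance = 1e-6)
})

test_that("effect coefficients are recovered on the CLR scale", {
  hits <- 0; total <- 0
  for (s in 1:40) {
    cfg <- sim_config(n_cags = 20, genes_per_cag = c(5, 10),
                      n_samples = 200, n_subjects = 200, effect_cags = 4,
                      effect_size = 1, gene_noise_sd = 0.1, seed = 7000 + s)
    sim <- simulate_cohort(cfg)
    catal <- sim$truth$catalog
    res <- fit_cag_pipeline(sim, catal)
    truth_lab <- vapply(seq_along(sim$truth$effect_sign), function(tc)
      unique(catal$gene[names(sim$truth$gene_cag)[
        sim$truth$gene_cag == tc]]), 0L)
    delta <- sim$truth$effect_sign * cfg$effect_size
    target <- delta - mean(delta)      # closure-adjusted CLR-scale truth
    est <- res$estimate[match(as.character(truth_lab), res$cag)]
    se <- res$se[match(as.character(truth_lab), res$cag)]
    eff <- sim$truth$effect_sign != 0
    hits <- hits + sum(abs(est[eff] - target[eff]) <= 3 * se[eff])
    total <- total + sum(eff)
  }
  expect_gte(hits / total, 0.95)
})

test_that("discovery thresholds are inclusive and empty-safe", {
  res <- data.frame(cag = c("0", "1", "2"), estimate = 1, se = 1,
                    p = c(0.01, 0.5, 0.9), model = "fixed",
                    q = c(0.2, 0.5, NA))
  expect_identical(discover(res), "0")   # q exactly 0.2 is included
  expect_identical(discover(res[0, ]), character(0))
})

test_that("validation requires sign agreement and recomputes q within the subset", {
  disc <- data.frame(cag = c("0", "1"), estimate = c(2, -2), se = 1,
                     p = c(0.001, 0.001), model = "fixed", q = c(0.01, 0.01))
  vali <- data.frame(cag = c("0", "1"), estimate = c(-1, -3), se = 1,
                     p = c(0.001, 0.001), model = "fixed", q = c(0.01, 0.01))
  rep1 <- suppressWarnings(validate_cags("0", disc, vali))
  expect_identical(rep1$validated, character(0))
  expect_equal(rep1$C2, 0)
  rep2 <- suppressWarnings(validate_cags(c("0", "1"), disc, vali))
  expect_identical(rep2$validated, "1")
  expect_equal(rep2$C1, 2); expect_equal(rep2$C2, 1)
  expect_error(suppressWarnings(validate_cags("7", disc, vali)), "missing")
  rep0 <- validate_cags(character(0), disc, vali)
  expect_equal(rep0$C1, 0)
  expect_equal(rep0$p_exact, 1)
})

test_that("strong planted effects are discovered and validated with correct signs", {
  sim <- simulate_paired_cohorts(sim_config(effect_size = 2, seed = 11))
  catal <- sim$truth$catalog
  rd <- fit_cag_pipeline(sim$discovery, catal)
  rv <- fit_cag_pipeline(sim$validation, catal)
  rep <- suppressWarnings(validate_cags(discover(rd), rd, rv))
  eff_tc <- which(sim$truth$effect_sign != 0)
  eff_ids <- vapply(eff_tc, function(tc)
    unique(catal$gene[names(sim$truth$gene_cag)[
      sim$truth$gene_cag == tc]]), 0L)
  expect_true(all(as.character(eff_ids) %in% rep$validated))
  est <- rd$estimate[match(as.character(eff_ids), rd$cag)]
  expect_equal(sign(est), unname(sign(sim$truth$effect_sign[eff_tc])))
})

test_that("the sign-agreement bound matches enumeration and its normal form", {
  # direct binomial-tail enumeration oracle for small C1
  enum_tail <- function(C1, C2) sum(choose(C1, C2:C1)) / 2^C1
  for (C1 in c(5, 12, 30)) {
    for (C2 in c(0, ceiling(C1 / 2), C1)) {
      expect_equal(sign_agreement_pvalue(C1, C2)$exact, enum_tail(C1, C2),
                   tolerance = 1e-12)
    }
  }
  expect_equal(sign_agreement_pvalue(10, 10)$exact, 2^-10)
  expect_equal(sign_agreement_pvalue(36, 18)$normal_approx, 0.5)
  expect_error(sign_agreement_pvalue(5, 6), "exceed")
})

test_that("the exact bound is conservative under the global null", {
  # C2 ~ Binomial(C1, 1/2) by construction; empirical type-I error <= alpha
  set.seed(77)
  C1 <- 40
  C2 <- rbinom(500, C1, 0.5)
  pv <- vapply(C2, function(x) sign_agreement_pvalue(C1, x)$exact, 0)
  for (alpha in c(0.05, 0.2)) expect_lte(mean(pv <= alpha), alpha)
})

test_that("representative-gene selection is deterministic and identity on singletons", {
  catal <- small_cag_catalog(5, 1)
  expect_identical(unname(select_representative_genes(catal, 1)),
                   unlist(catal$members, use.names = FALSE))
  catal2 <- small_cag_catalog(10, 4)
  s1 <- select_representative_genes(catal2, 3)
  expect_identical(s1, select_representative_genes(catal2, 3))
  expect_true(all(mapply(function(g, mem) g %in% mem, s1, catal2$members)))
})

test_that("sign_summary counts positive coefficients", {
  res <- data.frame(estimate = c(1, 2, -1, NA))
  expect_equal(sign_summary(res), 2 / 3)
  sim <- simulate_cohort(sim_config(n_cags = 12, genes_per_cag = c(2, 4),
                                    effect_cags = 0, seed = 30))
  r <- fit_cag_pipeline(sim, sim$truth$catalog)
  expect_gt(sign_summary(r), 0.1); expect_lt(sign_summary(r), 0.9)
})

test_that("annotation enrichment matches a hypergeometric enumeration oracle", {
  # brute-force two-sided Fisher p: sum of table probabilities <= observed
  fisher_oracle <- function(a, b, cc, d) {
    m <- a + cc; n <- b + d; k <- a + b
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  genes <- sprintf("g%02d", 1:20)
  target <- genes[1:10]
  ann <- data.frame(gene = genes[c(1:8, 11)], label = "L1")
  res <- annotation_enrichment(target, genes, ann, alpha = 0.01)
  expect_equal(res$p, fisher_oracle(8, 2, 1, 9), tolerance = 1e-9)
  # single label: Holm-Sidak decision reduces to p <= alpha
  expect_identical(res$significant, res$p <= 0.01)
  # equal frequency in target and background: OR 1, not significant
  ann2 <- data.frame(gene = genes[c(1:5, 11:15)], label = "L2")
  res2 <- annotation_enrichment(target, genes, ann2)
  expect_equal(res2$odds_ratio, 1, tolerance = 1e-9)
  expect_false(res2$significant)
  expect_error(annotation_enrichment(c(target, "zz"), genes, ann), "subset")
  expect_warning(
    annotation_enrichment(target, genes,
                          rbind(ann, data.frame(gene = "nope", label = "LX"))),
    "skipped")
})

test_that("Holm-Sidak step-down controls the family at the stated alpha", {
  genes <- sprintf("g%03d", 1:100)
  target <- genes[1:50]
  set.seed(10)
  ann <- do.call(rbind, lapply(1:6, function(i)
    data.frame(gene = sample(genes, 30), label = paste0("L", i))))
  res <- annotation_enrichment(target, genes, ann, alpha = 0.01)
  m <- nrow(res)
  expected <- pmin(1, cummax(1 - (1 - res$p)^(m - seq_len(m) + 1)))
  expect_equal(res$p_adjusted, expected)
  expect_true(all(diff(res$p_adjusted) >= -1e-15))
})
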