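make_prior <- function(d0, s2_prior_value) {
  structure(list(d0 = d0,
                 s2_prior = function(count) rep(s2_prior_value, length(count)),
                 trend = tibble::tibble(), span = 0.75, n_proteins = 0,
                 constant = TRUE),
            class = "nsp_var_prior")
}

test_that("per-protein replicate statistics follow the one-sample design", {
  r <- tibble::tibble(protein_group = c(rep("P1", 3), rep("P2", 2), "P3"),
                      gene = "G",
                      run = c("r1", "r2", "r3", "r1", "r2", "r1"),
                      log2_ratio = c(1, 1, 1, 0.9, 1.1, 5))
  s <- fit_protein_stats(r)
  expect_equal(s$log2_fc, c(1, 1, 5))
  expect_equal(s$s2, c(0, 0.02, NA))
  expect_identical(s$df, c(2L, 1L, 0L))
  # run restriction drops ratios outside the condition
  s2 <- fit_protein_stats(r, runs = c("r1", "r2"))
  expect_identical(s2$n, c(2L, 2L, 1L))
})

test_that("the squeeze formula and moderated t match hand evaluation", {
  stats <- tibble::tibble(protein_group = "P1", gene = "G", n = 3L,
                          log2_fc = 1, s2 = 0.04, df = 2L, n_precursors = 5L)
  out <- moderate_and_test(stats, make_prior(2, 0.01))
  expect_equal(out$s2_post, 0.025)                      # (2*.01 + 2*.04)/4
  expect_equal(out$t_mod, 10.954451150103322)
  expect_equal(out$p, 0.0003944922325233163)            # t with 4 df, frozen
})

test_that("moderation limits reduce to the ordinary t and full shrinkage", {
  set.seed(2)
  stats <- tibble::tibble(protein_group = sprintf("P%02d", 1:10), gene = "G",
                          n = 3L, log2_fc = rnorm(10),
                          s2 = rchisq(10, 2) / 20, df = 2L,
                          n_precursors = sample(1:9, 10, TRUE))
  none <- moderate_and_test(stats, make_prior(0, 0.01))
  expect_equal(none$t_mod, stats$log2_fc / sqrt(stats$s2 / 3))
  full <- moderate_and_test(stats, make_prior(Inf, 0.01))
  expect_equal(full$s2_post, rep(0.01, 10))
  # t_mod is continuous and monotone in d0 between the limits
  ts <- vapply(c(0, 0.5, 1, 2, 8, 64, 1e6, Inf), function(d0) {
    moderate_and_test(stats[1, ], make_prior(d0, 0.01))$t_mod
  }, numeric(1))
  expect_true(all(diff(ts) > 0) || all(diff(ts) < 0))
  expect_equal(ts[1], none$t_mod[1])
  expect_equal(ts[length(ts)], full$t_mod[1])
})

test_that("degenerate inputs give a pooled prior with infinite d0", {
  stats <- tibble::tibble(protein_group = sprintf("P%02d", 1:30), gene = "G",
                          n = 3L, log2_fc = 0, s2 = 0.04, df = 2L,
                          n_precursors = 4L)
  prior <- estimate_variance_prior(stats)
  expect_identical(prior$d0, Inf)
  expect_equal(prior$s2_prior(4), 0.04)
  expect_true(prior$constant)
  out <- moderate_and_test(stats, prior)
  expect_equal(out$s2_post, rep(0.04, 30))
  expect_error(estimate_variance_prior(stats[1:5, ]), "at least")
})

test_that("constant-count priors agree with limma's moments estimator", {
  skip_if_not_installed("limma")
  set.seed(42)
  n <- 800
  d0_true <- 4
  s0 <- 0.03
  sigma2 <- s0 * d0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, 2) / 2
  stats <- tibble::tibble(protein_group = sprintf("P%04d", 1:n), gene = "G",
                          n = 3L, log2_fc = 0, s2 = s2, df = 2L,
                          n_precursors = 7L)
  prior <- estimate_variance_prior(stats)
  ref <- limma::fitFDist(s2, df1 = 2)
  expect_equal(prior$d0, ref$df2, tolerance = 1e-6)
  expect_equal(prior$s2_prior(7), ref$scale, tolerance = 1e-6)
})

test_that("the count trend and prior df are recovered from simulation", {
  set.seed(77)
  n <- 2000
  d0_true <- 4
  counts <- sample(1:40, n, replace = TRUE)
  trend <- function(c) 0.08 / c^0.6          # variance falls with coverage
  sigma2 <- trend(counts) * d0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, 2) / 2
  stats <- tibble::tibble(protein_group = sprintf("P%04d", 1:n), gene = "G",
                          n = 3L, log2_fc = 0, s2 = s2, df = 2L,
                          n_precursors = counts)
  prior <- estimate_variance_prior(stats)
  expect_lt(abs(prior$d0 - d0_true) / d0_true, 0.25)
  rel <- abs(log(prior$s2_prior(counts) / trend(counts)))
  expect_lt(median(rel), log(1.25))
})

test_that("null p-values are uniform enough at 5 percent", {
  set.seed(5)
  n <- 2000
  counts <- sample(1:30, n, replace = TRUE)
  sigma <- sqrt(0.05 / counts^0.5)
  ratios <- tibble::tibble(
    protein_group = rep(sprintf("P%04d", 1:n), each = 3),
    gene = "G",
    run = rep(c("r1", "r2", "r3"), n),
    log2_ratio = rnorm(3 * n, 0, rep(sigma, each = 3)))
  pc <- tibble::tibble(protein_group = sprintf("P%04d", 1:n),
                       n_precursors = counts)
  fit <- moderated_de(ratios, pc)
  frac <- mean(fit$results$p < 0.05, na.rm = TRUE)
  ci <- qbinom(c(0.005, 0.995), n, 0.05) / n
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("moderation beats the plain t-test at matched empirical FDR", {
  set.seed(8)
  n <- 2000
  regulated <- runif(n) < 0.10
  counts <- sample(1:30, n, replace = TRUE)
  sigma <- sqrt(0.25^2 * 2 / counts)         # ratio noise falls with coverage
  fc_true <- ifelse(regulated, sample(c(-1, 1), n, TRUE), 0)
  vals <- matrix(rnorm(3 * n, rep(fc_true, each = 3),
                       rep(sigma, each = 3)), ncol = 3, byrow = TRUE)
  ratios <- tibble::tibble(
    protein_group = rep(sprintf("P%04d", 1:n), each = 3),
    gene = "G", run = rep(c("r1", "r2", "r3"), n),
    log2_ratio = as.numeric(t(vals)))
  pc <- tibble::tibble(protein_group = sprintf("P%04d", 1:n),
                       n_precursors = counts)
  fit <- moderated_de(ratios, pc)
  res <- fit$results[match(sprintf("P%04d", 1:n), fit$results$protein_group), ]
  p_plain <- apply(vals, 1, function(v) stats::t.test(v)$p.value)

  tp_at_fdr <- function(p, truth, fdr = 0.05) {
    o <- order(p)
    fd <- cumsum(!truth[o]) / seq_along(o)
    ok <- which(fd <= fdr)
    if (length(ok) == 0) return(0)
    sum(truth[o][seq_len(max(ok))])
  }
  expect_gt(tp_at_fdr(res$p, regulated), tp_at_fdr(p_plain, regulated))
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "0, 1")
  # order invariance
  set.seed(10)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("significance calls apply the volcano thresholds to unique groups", {
  res <- tibble::tibble(protein_group = c("P1", "P2", "P3", "P4;P5", "P6"),
                        log2_fc = c(1, 0.5, -1, 1.4, 0.7),
                        p_adj = c(0.01, 0.01, 0.04, 0.001, NA))
  out <- call_significance(res)
  expect_identical(out$call, c("up", "ns", "down", "ns", "not_tested"))
  expect_false(out$significant_up[4])     # multi-accession group ineligible
  expect_identical(out$unique_group, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("tidy and glance summarise a fitted DE object", {
  set.seed(3)
  n <- 60L
  ratios <- tibble::tibble(
    protein_group = rep(sprintf("P%02d", 1:n), each = 3),
    gene = rep(sprintf("G%02d", 1:n), each = 3),
    run = rep(c("r1", "r2", "r3"), n),
    log2_ratio = rnorm(3 * n, 0, 0.2))
  pc <- tibble::tibble(protein_group = sprintf("P%02d", 1:n),
                       n_precursors = sample(1:10, n, TRUE))
  fit <- moderated_de(ratios, pc)
  td <- tidy(fit)
  expect_identical(nrow(td), n)
  expect_true(all(c("log2_fc", "t_mod", "p", "p_adj", "call") %in% names(td)))
  g <- glance(fit)
  expect_identical(g$n_tested, sum(!is.na(fit$results$p)))
  expect_s3_class(autoplot(fit), "ggplot")
})
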