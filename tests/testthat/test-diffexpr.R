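test_that("gene-wise statistics match direct formulas", {
  # constant replicates
  m <- matrix(rep(1, 4), nrow = 1)
  gs <- genewise_stats(m)
  expect_equal(gs$effect, 1)
  expect_equal(gs$s2, 0)
  expect_identical(gs$df, 3L)
  expect_identical(attr(gs, "n_eff"), 4L)

  # two replicates [0, 2]: effect 1, s2 2, df 1
  gs2 <- genewise_stats(matrix(c(0, 2), nrow = 1))
  expect_equal(gs2$effect, 1)
  expect_equal(gs2$s2, 2)
  expect_identical(gs2$df, 1L)

  # noiseless two-group design with declared orientation
  mg <- matrix(c(0, 0, 1, 1), nrow = 1)
  gsa <- genewise_stats(mg, groups = c("a", "a", "b", "b"))
  expect_equal(gsa$effect, -1)
  expect_equal(gsa$s2, 0)
  expect_identical(gsa$df, 2L)
  expect_equal(attr(gsa, "n_eff"), 1)
  gsb <- genewise_stats(mg, groups = factor(c("a", "a", "b", "b"),
                                            levels = c("b", "a")))
  expect_equal(gsb$effect, 1)
  expect_equal(gsb$mean_b, 1)
  expect_equal(gsb$mean_a, 0)

  expect_error(genewise_stats(mg, groups = c("a", "a", "a", "b")),
               ">= 2 samples")
})

test_that("prior estimation recovers known hyperparameters", {
  # zero-dispersion limit: identical variances give an infinite prior df
  # and the common value as prior variance
  gs <- data.frame(gene_id = sprintf("g%03d", 1:50), effect = 0,
                   s2 = 0.25, df = 3L)
  pr <- estimate_prior(gs)
  expect_identical(pr$d0, Inf)
  expect_equal(pr$s0_2, 0.25)

  # parameter recovery under the full hierarchy
  set.seed(42)
  n <- 10000; d0_true <- 4; s0_true <- 0.04; df <- 4L
  sigma2 <- s0_true * d0_true / rchisq(n, d0_true)
  s2 <- sigma2 * rchisq(n, df) / df
  gsr <- data.frame(gene_id = sprintf("g%05d", 1:n), effect = 0,
                    s2 = s2, df = df)
  prr <- estimate_prior(gsr)
  expect_lt(abs(prr$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(prr$s0_2 - s0_true) / s0_true, 0.10)

  # scale equivariance: doubling every s2 doubles s0_2, d0 unchanged
  gsd <- gsr; gsd$s2 <- 2 * gsd$s2
  prd <- estimate_prior(gsd)
  expect_equal(prd$d0, prr$d0, tolerance = 1e-8)
  expect_equal(prd$s0_2, 2 * prr$s0_2, tolerance = 1e-8)

  gs0 <- data.frame(gene_id = "g1", effect = 0, s2 = 0, df = 3L)
  expect_error(estimate_prior(gs0), "degenerate")
})

test_that("moderated t matches a straight-from-formula oracle", {
  set.seed(7)
  n <- 50
  stats <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      effect = rnorm(n, 0, 1),
                      s2 = 0.04 * rchisq(n, 3) / 3,
                      df = 3L)
  prior <- list(d0 = 5.5, s0_2 = 0.05)
  got <- moderated_t(stats, prior, n_eff = 4)
  # independent evaluation straight from the definition
  s_tilde2 <- (prior$d0 * prior$s0_2 + stats$df * stats$s2) /
    (prior$d0 + stats$df)
  t_want <- stats$effect / sqrt(s_tilde2 / 4)
  p_want <- 2 * pt(-abs(t_want), df = prior$d0 + stats$df)
  expect_equal(got$t_mod, t_want, tolerance = 1e-10)
  expect_equal(got$p, p_want, tolerance = 1e-10)

  # null effect
  stats0 <- data.frame(gene_id = "g1", effect = 0, s2 = 0.1, df = 3L)
  out0 <- moderated_t(stats0, prior, n_eff = 4)
  expect_equal(out0$t_mod, 0)
  expect_equal(out0$p, 1)
})

test_that("moderated t limits: ordinary t at d0 = 0, z at d0 = Inf", {
  set.seed(11)
  n <- 20
  stats <- data.frame(gene_id = sprintf("g%02d", 1:n),
                      effect = rnorm(n),
                      s2 = 0.09 * rchisq(n, 3) / 3,
                      df = 3L)
  # d0 = 0: no moderation, ordinary gene-wise t
  got0 <- moderated_t(stats, list(d0 = 0, s0_2 = 1), n_eff = 4)
  t_ord <- stats$effect / sqrt(stats$s2 / 4)
  expect_equal(got0$t_mod, t_ord, tolerance = 1e-12)
  expect_equal(got0$p, 2 * pt(-abs(t_ord), df = 3), tolerance = 1e-12)

  # d0 = Inf with common variance: z-test against the standard normal
  s0 <- 0.04
  gotI <- moderated_t(stats, list(d0 = Inf, s0_2 = s0), n_eff = 4)
  z <- stats$effect / sqrt(s0 / 4)
  expect_equal(gotI$t_mod, z, tolerance = 1e-12)
  expect_equal(gotI$p, 2 * pnorm(-abs(z)), tolerance = 1e-12)

  expect_error(
    moderated_t(data.frame(gene_id = "g1", effect = 1, s2 = 0, df = 3L),
                list(d0 = 0, s0_2 = 1), n_eff = 4),
    "nonpositive posterior variance")
})

test_that("moderation shrinks |t| between the gene-wise and prior t", {
  set.seed(13)
  n <- 200
  sigma2 <- 0.05 * 3 / rchisq(n, 3)  # real variance dispersion
  stats <- data.frame(gene_id = sprintf("g%03d", 1:n),
                      effect = rnorm(n),
                      s2 = sigma2 * rchisq(n, 3) / 3,
                      df = 3L)
  prior <- estimate_prior(stats)
  expect_true(is.finite(prior$d0))
  tm <- abs(moderated_t(stats, prior, 4)$t_mod)
  t_gene <- abs(stats$effect / sqrt(stats$s2 / 4))
  t_prior <- abs(stats$effect / sqrt(prior$s0_2 / 4))
  expect_true(all(tm >= pmin(t_gene, t_prior) - 1e-12))
  expect_true(all(tm <= pmax(t_gene, t_prior) + 1e-12))
})

test_that("the full two-group path agrees with an independent
           empirical-Bayes implementation", {
  set.seed(9)
  n <- 300
  sigma2 <- 0.04 * 4 / rchisq(n, 4)
  mu <- rnorm(n, 8, 1)
  mat <- sapply(1:6, function(j) mu + rnorm(n, 0, sqrt(sigma2)))
  rownames(mat) <- sprintf("g%03d", 1:n)
  gs <- genewise_stats(mat, groups = rep(c("a", "b"), each = 3))
  pr <- estimate_prior(gs)
  mt <- moderated_t(gs, pr)

  fit <- limma::eBayes(limma::lmFit(mat, cbind(1, rep(c(1, 0), each = 3))))
  expect_equal(pr$d0, fit$df.prior, tolerance = 1e-9)
  expect_equal(pr$s0_2, fit$s2.prior, tolerance = 1e-9)
  expect_equal(mt$t_mod, unname(fit$t[, 2]), tolerance = 1e-9)
  expect_equal(mt$p, unname(fit$p.value[, 2]), tolerance = 1e-9)
})

test_that("BH adjustment matches the step-up definition", {
  # direct step-up evaluation
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")

  # independent step-up oracle on random p-values
  set.seed(21)
  p <- runif(40)^2
  got <- bh_adjust(p)
  m <- length(p)
  o <- order(p)
  adj_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  want <- pmin(1, adj_sorted)[match(seq_len(m), o)]
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= p))
  # adjusted values respect the p ordering
  expect_true(all(diff(got[o]) >= -1e-12))
})

test_that("few genes at adjusted p < 0.01 under the null", {
  # no planted effects: Type-I control of the moderated test
  frac <- vapply(1:5, function(s) {
    set.seed(300 + s)
    n <- 800
    mat <- matrix(rnorm(n * 6, 8, 0.3), n)
    rownames(mat) <- sprintf("g%04d", 1:n)
    gs <- genewise_stats(mat, groups = rep(c("a", "b"), each = 3))
    mt <- moderated_t(gs, estimate_prior(gs))
    mean(bh_adjust(mt$p) < 0.01)
  }, 0)
  expect_true(all(frac <= 0.02))
})

test_that("DE drivers handle the exact noise-free limit", {
  atl <- small_atlas()
  mix <- default_mixtures()
  arrs <- simulate_two_color(atl, mix$germarium, mix$testis_apex,
                             noise_log2_sd = 0, dye_bias_coeffs = 0,
                             seed = 2)
  de <- de_two_color(loess_normalize(ma_table(arrs)))
  true_m <- unname(log2(mix_expression(atl, mix$germarium) /
                          mix_expression(atl, mix$testis_apex)))
  expect_equal(de$M, true_m)
  expect_identical(unique(de$p[de$M != 0]), 0)
  expect_identical(unique(de$p[de$M == 0]), 1)
  expect_true(all(de$p_adj >= de$p))
})
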