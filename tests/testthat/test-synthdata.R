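test_that("atlas construction is deterministic and respects proportions", {
  a1 <- build_atlas(small_config(seed = 7))
  a2 <- build_atlas(small_config(seed = 7))
  expect_identical(a1, a2)
  a3 <- build_atlas(small_config(seed = 8))
  expect_false(identical(a1$true_expression, a3$true_expression))

  # exact apportionment of class labels
  cfg <- atlas_config(n_genes = 1000,
                      class_proportions = c(shared_gsc = 0.05,
                                            housekeeping = 0.95))
  atl <- build_atlas(cfg)
  expect_identical(sum(atl$truth_class == "shared_gsc"), 50L)
  expect_identical(sum(atl$truth_class == "housekeeping"), 950L)
})

test_that("planted enrichments have the configured magnitude", {
  atl <- build_atlas(small_config(effect_log2fc = 2))
  expect_true(all(atl$true_expression >= 0))
  shared <- atl$truth_class == "shared_gsc"
  ratio_f <- atl$true_expression[shared, "female_gsc"] /
    atl$true_expression[shared, "kc_reference"]
  ratio_m <- atl$true_expression[shared, "male_gsc_gonialblast"] /
    atl$true_expression[shared, "kc_reference"]
  expect_equal(unname(ratio_f), rep(4, sum(shared)))
  expect_equal(unname(ratio_m), rep(4, sum(shared)))
  # shared_gsc elevated relative to differentiating populations too
  expect_true(all(atl$true_expression[shared, "female_gsc"] >
                    atl$true_expression[shared, "female_diff_germ"]))

  # low_expressed genes stay under the 64-intensity gate in gonadal
  # populations
  low <- atl$truth_class == "low_expressed"
  gonadal <- setdiff(atl$populations, "kc_reference")
  expect_true(all(atl$true_expression[low, gonadal] < 64))
})

test_that("atlas config validation names the offending field", {
  expect_error(atlas_config(class_proportions = c(shared_gsc = 0.5,
                                                  housekeeping = 0.6)),
               "class_proportions.*sum to 1")
  expect_error(atlas_config(class_proportions = c(not_a_class = 1)),
               "unknown class")
  expect_error(atlas_config(effect_log2fc = 0), "effect_log2fc")
  expect_error(atlas_config(baseline_log2_sd = -1), "baseline_log2_sd")
})

test_that("mix_expression is the weighted sum of population means", {
  atl <- small_atlas()
  # identity mixture returns the population column exactly
  one <- mixture_design("pure", c(female_gsc = 1))
  expect_equal(mix_expression(atl, one),
               atl$true_expression[, "female_gsc"])

  # equal weights over two populations average their means
  expr <- matrix(c(10, 30), nrow = 1,
                 dimnames = list("g001", c("female_gsc", "kc_reference")))
  tiny <- manual_atlas(expr)
  half <- mixture_design("half", c(female_gsc = 0.5, kc_reference = 0.5))
  expect_equal(unname(mix_expression(tiny, half)), 20)

  # an all-zero gene stays zero in any mixture
  expr0 <- matrix(0, nrow = 1, ncol = 2,
                  dimnames = list("g001", c("female_gsc", "kc_reference")))
  expect_equal(unname(mix_expression(manual_atlas(expr0), half)), 0)

  bad <- structure(list(sample_name = "x", weights = c(nonsense = 1)),
                   class = "mixture_design")
  expect_error(mix_expression(atl, bad), "valid populations")
})

test_that("two-color simulation: noiseless fidelity and dye-flip geometry", {
  atl <- small_atlas()
  mix <- default_mixtures()
  mu_g <- mix_expression(atl, mix$germarium)
  mu_t <- mix_expression(atl, mix$testis_apex)

  arr <- simulate_two_color(atl, mix$germarium, mix$testis_apex,
                            n_reps = 4, n_flips = 2, noise_log2_sd = 0,
                            dye_bias_coeffs = 0, seed = 5)
  expect_length(arr, 4)
  expect_identical(vapply(arr, `[[`, NA, "dye_flipped"),
                   c(TRUE, TRUE, FALSE, FALSE))
  # unflipped arrays carry germarium in channel 1
  expect_equal(arr[[3]]$intensity_ch1 / arr[[3]]$intensity_ch2,
               unname(mu_g / mu_t))
  # flipped arrays are inverted in channel space
  expect_equal(arr[[1]]$intensity_ch1 / arr[[1]]$intensity_ch2,
               unname(mu_t / mu_g))

  # constant dye bias: +0.5 on unflipped M, -0.5 on flipped M
  arrb <- simulate_two_color(atl, mix$germarium, mix$testis_apex,
                             n_reps = 2, n_flips = 1, noise_log2_sd = 0,
                             dye_bias_coeffs = 0.5, seed = 5)
  m_flip <- compute_ma(arrb[[1]])$M
  m_unflip <- compute_ma(arrb[[2]])$M
  true_m <- unname(log2(mu_g / mu_t))
  expect_equal(m_unflip, true_m + 0.5)
  expect_equal(m_flip, true_m - 0.5)

  # seeded determinism
  expect_identical(
    simulate_two_color(atl, mix$germarium, mix$testis_apex, seed = 11),
    simulate_two_color(atl, mix$germarium, mix$testis_apex, seed = 11))

  expect_error(simulate_two_color(atl, mix$germarium, mix$testis_apex,
                                  n_reps = 2, n_flips = 3), "n_flips")
  expect_error(simulate_two_color(atl, mix$germarium, mix$testis_apex,
                                  noise_log2_sd = -0.1), "noise_log2_sd")
})

test_that("dye-flip symmetry cancels odd-in-dye bias at zero noise", {
  atl <- small_atlas()
  mix <- default_mixtures()
  true_m <- unname(log2(mix_expression(atl, mix$germarium) /
                          mix_expression(atl, mix$testis_apex)))
  arr <- simulate_two_color(atl, mix$germarium, mix$testis_apex,
                            n_reps = 4, n_flips = 2, noise_log2_sd = 0,
                            dye_bias_coeffs = c(1, -0.1), seed = 2)
  m <- sapply(arr, function(a) compute_ma(a)$M)
  # averaging over the flip-balanced design cancels the bias exactly:
  # the bias polynomial is evaluated at the same A on both orientations
  expect_equal(rowMeans(m), true_m, tolerance = 1e-12)
})

test_that("single-channel simulation: group structure and determinism", {
  atl <- small_atlas()
  mix <- default_mixtures()
  scs <- simulate_single_channel(
    atl, list(female_gsc = mix$female_gsc, kc = mix$kc),
    n_per_group = 3, noise_log2_sd = 0,
    experiment_tag = "female_gsc_vs_kc", seed = 4)
  expect_identical(scs$group_labels, rep(c("female_gsc", "kc"), each = 3))
  # noiseless replicates within a group are identical
  expect_equal(scs$matrix[, 1], scs$matrix[, 2])
  expect_equal(scs$matrix[, 4], scs$matrix[, 6])
  # pure mixtures: group log2 difference equals the planted effect for
  # shared_gsc genes
  shared <- atl$truth_class == "shared_gsc"
  diffs <- log2(scs$matrix[shared, 1]) - log2(scs$matrix[shared, 4])
  expect_equal(unname(diffs),
               rep(atl$config$effect_log2fc, sum(shared)))

  expect_identical(
    simulate_single_channel(atl, list(a = mix$os_bgcn, b = mix$bgcn),
                            experiment_tag = "os_bgcn_vs_bgcn", seed = 9),
    simulate_single_channel(atl, list(a = mix$os_bgcn, b = mix$bgcn),
                            experiment_tag = "os_bgcn_vs_bgcn", seed = 9))

  expect_error(
    simulate_single_channel(atl, list(a = mix$os_bgcn, b = mix$bgcn),
                            n_per_group = 1,
                            experiment_tag = "os_bgcn_vs_bgcn"),
    "n_per_group")
})

test_that("planted contrast is recovered on average under noise", {
  mix <- default_mixtures()
  for (s in 1:3) {
    atl <- small_atlas(seed = s)
    noise <- 0.2
    scs <- simulate_single_channel(
      atl, list(female_gsc = mix$female_gsc, kc = mix$kc),
      n_per_group = 3, noise_log2_sd = noise,
      experiment_tag = "female_gsc_vs_kc", seed = 100 + s)
    shared <- atl$truth_class == "shared_gsc"
    n_sh <- sum(shared)
    d <- rowMeans(log2(scs$matrix[shared, 1:3])) -
      rowMeans(log2(scs$matrix[shared, 4:6]))
    se <- noise * sqrt(2 / 3) / sqrt(n_sh)
    expect_lt(abs(mean(d) - atl$config$effect_log2fc), 3 * se)
  }
})

test_that("truth_sets partitions the gene universe", {
  atl <- small_atlas()
  ts <- truth_sets(atl)
  expect_setequal_strict(unlist(ts, use.names = FALSE), atl$gene_ids)
  expect_identical(sum(lengths(ts)), length(atl$gene_ids))
  expect_identical(anyDuplicated(unlist(ts, use.names = FALSE)), 0L)

  # counts follow the configured proportions; absent classes are present
  # as empty sets
  cfg <- atlas_config(n_genes = 1000,
                      class_proportions = c(shared_gsc = 0.05,
                                            housekeeping = 0.95))
  ts2 <- truth_sets(build_atlas(cfg))
  expect_length(ts2$shared_gsc, 50)
  expect_length(ts2$low_expressed, 0)
  expect_setequal_strict(names(ts2), TRUTH_CLASSES)
})
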