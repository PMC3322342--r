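#!/usr/bin/env Rscript
# Stage 3 — empirical-Bayes moderated t-tests for the three comparisons.
#
# Fits gene-wise effects and variances, shrinks variances toward a
# moment-matched prior, and reports moderated t / BH-adjusted p per gene:
#   E1 germarium vs testis apex   (positive M = germarium-enriched)
#   E2 female GSC vs Kc cells     (positive M = GSC-enriched)
#   E3 Os+ bgcn- vs bgcn- testes  (positive M = Os+ bgcn- -enriched)

suppressPackageStartupMessages(library(gscatlas))
ROOT_SEED <- 1
out <- "results/03_de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(seed = ROOT_SEED)
acfg <- cfg$atlas
acfg$seed <- gscatlas:::stage_seed(ROOT_SEED, "atlas")
atlas <- build_atlas(acfg)
mix <- cfg$mixtures

arrays <- simulate_two_color(atlas, mix$germarium, mix$testis_apex,
                             n_reps = cfg$two_color$n_reps,
                             n_flips = cfg$two_color$n_flips,
                             noise_log2_sd = cfg$two_color$noise_log2_sd,
                             dye_bias_coeffs = cfg$two_color$dye_bias_coeffs,
                             seed = gscatlas:::stage_seed(ROOT_SEED,
                                                          "two_color"))
ma <- loess_normalize(ma_table(arrays), span = cfg$loess$span,
                      iterations = cfg$loess$iterations)
e2 <- simulate_single_channel(
  atlas, list(female_gsc = mix$female_gsc, kc = mix$kc),
  n_per_group = cfg$single_channel$n_per_group,
  noise_log2_sd = cfg$single_channel$noise_log2_sd,
  experiment_tag = "female_gsc_vs_kc",
  seed = gscatlas:::stage_seed(ROOT_SEED, "female_gsc"))
e3 <- simulate_single_channel(
  atlas, list(os_bgcn = mix$os_bgcn, bgcn = mix$bgcn),
  n_per_group = cfg$single_channel$n_per_group,
  noise_log2_sd = cfg$single_channel$noise_log2_sd,
  experiment_tag = "os_bgcn_vs_bgcn",
  seed = gscatlas:::stage_seed(ROOT_SEED, "os_bgcn"))

de_e1 <- de_two_color(ma)
de_e2 <- de_two_group(e2, positive_group = "female_gsc")
de_e3 <- de_two_group(e3, positive_group = "os_bgcn")

for (x in list(list(de_e1, "de_germarium_vs_testis.tsv", "E1"),
               list(de_e2, "de_female_gsc_vs_kc.tsv", "E2"),
               list(de_e3, "de_os_bgcn_vs_bgcn.tsv", "E3"))) {
  de <- x[[1]]
  prior <- attr(de, "prior")
  cat(sprintf("%s: %d genes significant at FDR < %g (prior d0 %.1f, s0^2 %.4f); %s\n",
              x[[3]], sum(de$p_adj < cfg$filters$alpha), cfg$filters$alpha,
              prior$d0, prior$s0_2, attr(de, "orientation")))
  write_table(de, file.path(out, x[[2]]))
}
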