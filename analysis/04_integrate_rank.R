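#!/usr/bin/env Rscript
# Stage 4 — cross-dataset filters and rank-sum ordering.
#
# Reads the three DE tables from stage 3 and produces the three ranked
# candidate lists:
#   shared_gsc:        significant & enriched in BOTH stem-cell
#                      comparisons + >64 baseline intensity in both
#                      tissues; ordered by summed M ranks.
#   germarium_not_gsc: germarium-enriched minus female-GSC-enriched;
#                      ordered by germarium M.
#   testis_not_gsc:    testis-enriched minus Os+ bgcn- -enriched; ordered
#                      by summed ranks of |M_tissue| and ascending
#                      M_stem-cell (later-differentiating genes first).

suppressPackageStartupMessages(library(gscatlas))
out <- "results/04_filters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

de_dir <- "results/03_de"
if (!dir.exists(de_dir))
  stop("run analysis/03_differential_expression.R first", call. = FALSE)
de_e1 <- read_table(file.path(de_dir, "de_germarium_vs_testis.tsv"),
                    required = c("M", "p_adj", "mean_germarium",
                                 "mean_testis_apex"))
de_e2 <- read_table(file.path(de_dir, "de_female_gsc_vs_kc.tsv"),
                    required = c("M", "p_adj"))
de_e3 <- read_table(file.path(de_dir, "de_os_bgcn_vs_bgcn.tsv"),
                    required = c("M", "p_adj"))

cfg <- filter_config()
lists <- list(
  shared_gsc = filter_shared_gsc(de_e2, de_e3, de_e1, cfg),
  germarium_not_gsc = filter_germarium_not_gsc(de_e1, de_e2, cfg),
  testis_not_gsc = filter_testis_not_gsc(de_e1, de_e3, cfg))

for (nm in names(lists)) {
  rl <- lists[[nm]]
  cat(sprintf("filter %-18s: %4d genes; top 5: %s\n", nm, nrow(rl),
              paste(utils::head(rl$gene_id, 5), collapse = ", ")))
  write_table(as.data.frame(rl), file.path(out, sprintf("filter_%s.tsv", nm)))
}
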