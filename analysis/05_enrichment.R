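#!/usr/bin/env Rscript
# Stage 5 — hypergeometric term over-representation of the filter lists.
#
# Simulates generic annotations (random terms plus one planted term per
# truth class at 90% purity) and tests each ranked list against the
# all-genes background, flagging terms with BH-adjusted p < 0.01.

suppressPackageStartupMessages(library(gscatlas))
ROOT_SEED <- 1
out <- "results/05_enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- run_config(seed = ROOT_SEED)
acfg <- cfg$atlas
acfg$seed <- gscatlas:::stage_seed(ROOT_SEED, "atlas")
atlas <- build_atlas(acfg)
ann <- simulate_annotations(atlas, n_terms = cfg$enrichment$n_terms,
                            term_size_range = cfg$enrichment$term_size_range,
                            purity = cfg$enrichment$purity,
                            seed = gscatlas:::stage_seed(ROOT_SEED,
                                                         "annotations"))

filter_dir <- "results/04_filters"
if (!dir.exists(filter_dir))
  stop("run analysis/04_integrate_rank.R first", call. = FALSE)
for (nm in c("shared_gsc", "germarium_not_gsc", "testis_not_gsc")) {
  query <- read_table(file.path(filter_dir,
                                sprintf("filter_%s.tsv", nm)))$gene_id
  res <- overrepresentation(query, ann, alpha = 0.01)
  n_sig <- sum(res$significant)
  cat(sprintf("%-18s: %d/%d terms significant; top term %s (p_adj %.2e)\n",
              nm, n_sig, nrow(res), res$term_id[1], res$p_adj[1]))
  write_table(cbind(gene_set = nm, res),
              file.path(out, sprintf("enrichment_%s.tsv", nm)))
}
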