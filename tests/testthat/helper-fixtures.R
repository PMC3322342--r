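# Shared fixtures: small seeded configurations and hand-built tables.

small_config <- function(n_genes = 600, seed = 1, ...) {
  atlas_config(n_genes = n_genes, seed = seed, ...)
}

small_atlas <- function(n_genes = 600, seed = 1, ...) {
  build_atlas(small_config(n_genes = n_genes, seed = seed, ...))
}

# atlas whose A support is contiguous (no detached low-intensity cluster)
contiguous_config <- function(n_genes = 2000, seed = 1) {
  atlas_config(
    n_genes = n_genes, seed = seed,
    class_proportions = c(shared_gsc = 0.06, germarium_not_gsc = 0.06,
                          testis_not_gsc = 0.06, female_germ_general = 0.01,
                          male_germ_general = 0.01, housekeeping = 0.80))
}

# a hand-built atlas with explicit expression values, for exact arithmetic
manual_atlas <- function(expr, truth_class = rep("housekeeping", nrow(expr))) {
  structure(
    list(gene_ids = rownames(expr),
         populations = colnames(expr),
         true_expression = expr,
         truth_class = truth_class,
         config = atlas_config(n_genes = max(nrow(expr), 10))),
    class = "population_atlas")
}

# minimal DE table for integrate-stage tests
make_de <- function(gene_id, M, p_adj, ...) {
  df <- data.frame(gene_id = gene_id, M = M, A = 8, t_mod = sign(M) * 5,
                   p = p_adj / 2, p_adj = p_adj, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

# one two-color array built directly from channel intensities
manual_array <- function(ch1, ch2, flipped = FALSE,
                         ids = sprintf("g%03d", seq_along(ch1))) {
  structure(list(replicate_id = 1L, gene_ids = ids,
                 intensity_ch1 = ch1, intensity_ch2 = ch2,
                 dye_flipped = flipped),
            class = "two_color_array")
}

with_seed_query <- function(ids, n, seed) {
  set.seed(seed)
  sample(ids, n)
}

expect_setequal_strict <- function(got, want) {
  expect_true(setequal(got, want),
              info = sprintf("sets differ: %d extra, %d missing",
                             length(setdiff(got, want)),
                             length(setdiff(want, got))))
}
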