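#' Cell populations and planted truth classes
#'
#' The synthetic ground truth models seven cell populations of the
#' Drosophila gonad and its reference material: female germline stem cells
#' (GSCs), differentiating female germ cells, female somatic (niche) cells,
#' male GSCs/gonialblasts, differentiating male germ cells, male somatic
#' cells, and a Kc tissue-culture reference. Each simulated gene carries one
#' planted truth class describing where it is enriched.
#'
#' @format Character vectors of valid population and truth-class names.
#' @name populations
NULL

#' @rdname populations
#' @export
ATLAS_POPULATIONS <- c(
  "female_gsc", "female_diff_germ", "female_soma",
  "male_gsc_gonialblast", "male_diff_germ", "male_soma",
  "kc_reference"
)

#' @rdname populations
#' @export
TRUTH_CLASSES <- c(
  "shared_gsc", "germarium_not_gsc", "testis_not_gsc",
  "female_germ_general", "male_germ_general", "housekeeping",
  "low_expressed"
)

# populations in which each truth class is multiplicatively enriched
class_enriched_populations <- list(
  shared_gsc          = c("female_gsc", "male_gsc_gonialblast"),
  germarium_not_gsc   = c("female_diff_germ", "female_soma"),
  testis_not_gsc      = c("male_diff_germ", "male_soma"),
  female_germ_general = c("female_gsc", "female_diff_germ"),
  male_germ_general   = c("male_gsc_gonialblast", "male_diff_germ"),
  housekeeping        = character(0),
  low_expressed       = c("female_gsc", "male_gsc_gonialblast")
)

#' Configuration for a synthetic population expression atlas
#'
#' @param n_genes number of genes to simulate (>= 100 for default runs; the
#'   constructor enforces >= 10 so tiny unit-test atlases remain possible).
#' @param class_proportions named numeric vector mapping truth classes to
#'   fractions summing to 1. Classes omitted from the vector get zero genes.
#' @param baseline_log2_mean mean of the log2 baseline expression draw.
#' @param baseline_log2_sd standard deviation of the log2 baseline draw.
#' @param effect_log2fc planted enrichment magnitude in log2 units (> 0);
#'   class-defining populations are elevated by the factor
#'   `2^effect_log2fc`.
#' @param seed integer seed; atlas construction is fully deterministic.
#' @return An object of class `atlas_config`.
#' @export
atlas_config <- function(n_genes = 5000,
                         class_proportions = c(
                           shared_gsc          = 0.06,
                           germarium_not_gsc   = 0.06,
                           testis_not_gsc      = 0.06,
                           female_germ_general = 0.01,
                           male_germ_general   = 0.01,
                           low_expressed       = 0.05,
                           housekeeping        = 0.75
                         ),
                         baseline_log2_mean = 9,
                         baseline_log2_sd = 1,
                         effect_log2fc = 1.5,
                         seed = 1) {
  assert_count(n_genes, "n_genes", lower = 10L)
  if (is.null(names(class_proportions)) || any(names(class_proportions) == ""))
    stop("'class_proportions' must be a fully named numeric vector",
         call. = FALSE)
  unknown <- setdiff(names(class_proportions), TRUTH_CLASSES)
  if (length(unknown) > 0L)
    stop(sprintf("'class_proportions' has unknown class(es): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(TRUTH_CLASSES, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(names(class_proportions)))
    stop("'class_proportions' has duplicated class names", call. = FALSE)
  if (any(class_proportions < 0))
    stop("'class_proportions' must be nonnegative", call. = FALSE)
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop(sprintf(
      "'class_proportions' must sum to 1 within 1e-9 (got %.12f)",
      sum(class_proportions)), call. = FALSE)
  assert_scalar_number(baseline_log2_mean, "baseline_log2_mean")
  assert_scalar_number(baseline_log2_sd, "baseline_log2_sd", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(effect_log2fc, "effect_log2fc", lower = 0,
                       strict_lower = TRUE)
  assert_count(seed, "seed")
  structure(
    list(n_genes = as.integer(n_genes),
         class_proportions = class_proportions,
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         effect_log2fc = effect_log2fc,
         seed = as.integer(seed)),
    class = "atlas_config")
}

# Largest-remainder apportionment so class counts sum exactly to n and a
# proportion like 0.05 of 1000 gives exactly 50.
apportion_counts <- function(proportions, n) {
  raw <- proportions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Build a ground-truth population expression atlas
#'
#' Draws a log-normal baseline per gene (log2 mean/sd from the config),
#' replicates it across all populations, then elevates each truth class's
#' defining populations by the factor `2^effect_log2fc`. Genes in the
#' `low_expressed` class follow the `shared_gsc` enrichment pattern but
#' their baseline is drawn low and capped so that their linear-scale means
#' stay below 64 in every gonadal population; they exist to exercise the
#' downstream baseline-intensity gate.
#'
#' @param config an [atlas_config()].
#' @return An object of class `population_atlas` with fields `gene_ids`,
#'   `populations`, `true_expression` (gene x population matrix of
#'   linear-scale means), `truth_class`, and `config`.
#' @export
build_atlas <- function(config) {
  if (!inherits(config, "atlas_config"))
    stop("'config' must be an atlas_config object", call. = FALSE)
  n <- config$n_genes
  props <- config$class_proportions
  counts <- apportion_counts(props, n)
  truth_class <- rep(names(props), counts)
  gene_ids <- sprintf("g%05d", seq_len(n))

  atlas <- with_seed(config$seed, {
    log2_baseline <- stats::rnorm(n, config$baseline_log2_mean,
                                  config$baseline_log2_sd)
    low <- truth_class == "low_expressed"
    if (any(low)) {
      # cap keeps even the enriched populations of these genes below 64
      cap <- 6 - config$effect_log2fc - 0.1
      log2_baseline[low] <- pmin(stats::rnorm(sum(low), 3, 0.5), cap)
    }
    baseline <- 2^log2_baseline
    expr <- matrix(baseline, nrow = n, ncol = length(ATLAS_POPULATIONS),
                   dimnames = list(gene_ids, ATLAS_POPULATIONS))
    fc <- 2^config$effect_log2fc
    for (cls in unique(truth_class)) {
      pops <- class_enriched_populations[[cls]]
      if (length(pops) > 0L)
        expr[truth_class == cls, pops] <- expr[truth_class == cls, pops] * fc
    }
    expr
  })

  structure(
    list(gene_ids = gene_ids,
         populations = ATLAS_POPULATIONS,
         true_expression = atlas,
         truth_class = truth_class,
         config = config),
    class = "population_atlas")
}

#' @export
print.population_atlas <- function(x, ...) {
  cat(sprintf("population_atlas: %d genes x %d populations (seed %d)\n",
              length(x$gene_ids), length(x$populations), x$config$seed))
  tab <- table(factor(x$truth_class, levels = TRUTH_CLASSES))
  cat("truth classes:\n")
  print(tab)
  invisible(x)
}

#' Define a tissue sample as a weighted mixture of cell populations
#'
#' @param sample_name label for the mixture (e.g. `"germarium"`).
#' @param weights named nonnegative numeric vector over atlas populations,
#'   summing to 1 within 1e-9.
#' @return An object of class `mixture_design`.
#' @export
mixture_design <- function(sample_name, weights) {
  if (!is.character(sample_name) || length(sample_name) != 1L)
    stop("'sample_name' must be a single string", call. = FALSE)
  if (is.null(names(weights)) || any(names(weights) == ""))
    stop("'weights' must be a fully named numeric vector", call. = FALSE)
  unknown <- setdiff(names(weights), ATLAS_POPULATIONS)
  if (length(unknown) > 0L)
    stop(sprintf("unknown population(s) %s; valid populations are: %s",
                 paste(unknown, collapse = ", "),
                 paste(ATLAS_POPULATIONS, collapse = ", ")), call. = FALSE)
  if (any(weights < 0))
    stop("'weights' must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop(sprintf("'weights' must sum to 1 within 1e-9 (got %.12f)",
                 sum(weights)), call. = FALSE)
  structure(list(sample_name = sample_name, weights = weights),
            class = "mixture_design")
}

#' Default tissue and experiment mixtures
#'
#' Wild-type germarium and testis-apex mixtures contain a small stem-cell
#' fraction plus differentiating germline and somatic cells (female and male
#' populations never co-occur in one tissue). The single-channel experiment
#' mixtures model FACS-purified female GSC-like germ cells vs Kc cells, and
#' Os-overexpressing bgcn-mutant testes (stem-cell/gonialblast enriched) vs
#' bgcn-mutant testes.
#'
#' @return Named list of [mixture_design()] objects: `germarium`,
#'   `testis_apex`, `female_gsc`, `kc`, `os_bgcn`, `bgcn`.
#' @export
default_mixtures <- function() {
  list(
    germarium = mixture_design("germarium", c(
      female_gsc = 0.1, female_diff_germ = 0.5, female_soma = 0.4)),
    testis_apex = mixture_design("testis_apex", c(
      male_gsc_gonialblast = 0.2, male_diff_germ = 0.5, male_soma = 0.3)),
    female_gsc = mixture_design("female_gsc", c(female_gsc = 1)),
    kc = mixture_design("kc", c(kc_reference = 1)),
    os_bgcn = mixture_design("os_bgcn", c(
      male_gsc_gonialblast = 0.8, male_diff_germ = 0.1, male_soma = 0.1)),
    bgcn = mixture_design("bgcn", c(
      male_gsc_gonialblast = 0.3, male_diff_germ = 0.4, male_soma = 0.3))
  )
}

#' Expected expression of a population mixture
#'
#' @param atlas a [build_atlas()] result.
#' @param design a [mixture_design()].
#' @return Named numeric vector (one entry per gene) of expected
#'   linear-scale expression: the weighted sum of population means.
#' @export
mix_expression <- function(atlas, design) {
  if (!inherits(atlas, "population_atlas"))
    stop("'atlas' must be a population_atlas", call. = FALSE)
  if (!inherits(design, "mixture_design"))
    stop("'design' must be a mixture_design", call. = FALSE)
  unknown <- setdiff(names(design$weights), atlas$populations)
  if (length(unknown) > 0L)
    stop(sprintf("unknown population(s) %s; valid populations are: %s",
                 paste(unknown, collapse = ", "),
                 paste(atlas$populations, collapse = ", ")), call. = FALSE)
  drop(atlas$true_expression[, names(design$weights), drop = FALSE] %*%
         design$weights)
}

#' Simulate replicated two-color arrays with dye swaps and dye bias
#'
#' Each replicate hybridization measures the germarium and testis-apex
#' mixtures in two channels. Channel intensities are the mixture
#' expectations under independent multiplicative log-normal noise
#' (`noise_log2_sd` on the log2 scale). A smooth intensity-dependent dye
#' bias `polyval(dye_bias_coeffs, A)` (A = mean log2 intensity) is added to
#' the log2 channel-1/channel-2 ratio, split symmetrically across the two
#' channels so A is unchanged. Because the bias follows the dyes, its sign
#' relative to the germarium/testis contrast inverts on dye-flipped arrays.
#' The first `n_flips` replicates are dye-flipped (germarium labeled in
#' channel 2).
#'
#' @param atlas a [build_atlas()] result.
#' @param germarium_mix,testis_mix [mixture_design()]s for the two tissues.
#' @param n_reps number of replicate arrays (default 4).
#' @param n_flips number of dye-flipped replicates (default 2; must be
#'   <= `n_reps`).
#' @param noise_log2_sd nonnegative log2-scale noise standard deviation.
#' @param dye_bias_coeffs polynomial coefficients over A, constant first;
#'   `0` means no dye bias.
#' @param seed integer seed.
#' @return List of `two_color_array` objects with fields `replicate_id`,
#'   `gene_ids`, `intensity_ch1`, `intensity_ch2`, `dye_flipped`.
#' @export
simulate_two_color <- function(atlas, germarium_mix, testis_mix,
                               n_reps = 4, n_flips = 2,
                               noise_log2_sd = 0.35,
                               dye_bias_coeffs = 0, seed = 1) {
  assert_count(n_reps, "n_reps", lower = 2L)
  assert_count(n_flips, "n_flips", lower = 0L)
  if (n_flips > n_reps)
    stop(sprintf("'n_flips' (%d) must be <= 'n_reps' (%d)",
                 n_flips, n_reps), call. = FALSE)
  assert_scalar_number(noise_log2_sd, "noise_log2_sd", lower = 0)
  assert_count(seed, "seed")
  mu_g <- mix_expression(atlas, germarium_mix)
  mu_t <- mix_expression(atlas, testis_mix)
  n <- length(mu_g)

  with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      g <- mu_g * 2^stats::rnorm(n, 0, noise_log2_sd)
      t <- mu_t * 2^stats::rnorm(n, 0, noise_log2_sd)
      flipped <- r <= n_flips
      ch1 <- if (flipped) t else g
      ch2 <- if (flipped) g else t
      a <- (log2(ch1) + log2(ch2)) / 2
      delta <- polyval(dye_bias_coeffs, a)
      structure(
        list(replicate_id = r,
             gene_ids = atlas$gene_ids,
             intensity_ch1 = unname(ch1 * 2^(delta / 2)),
             intensity_ch2 = unname(ch2 * 2^(-delta / 2)),
             dye_flipped = flipped),
        class = "two_color_array")
    })
  })
}

#' Simulate a two-group single-channel experiment
#'
#' Each sample is its group's mixture expectation under independent
#' multiplicative log-normal noise. Used to emulate the two external
#' stem-cell datasets: FACS-purified female GSC-like cells vs Kc cells, and
#' Os+ bgcn- vs bgcn- testes.
#'
#' @param atlas a [build_atlas()] result.
#' @param group_mixes named list of exactly two [mixture_design()]s; names
#'   become the group labels, in order (group 1, group 2).
#' @param n_per_group samples per group (>= 2; variance is undefined
#'   downstream otherwise).
#' @param noise_log2_sd nonnegative log2-scale noise standard deviation.
#' @param experiment_tag `"female_gsc_vs_kc"` or `"os_bgcn_vs_bgcn"`.
#' @param seed integer seed.
#' @return A `single_channel_set`: `matrix` (gene x sample positive linear
#'   intensities), `group_labels`, `experiment_tag`, `gene_ids`.
#' @export
simulate_single_channel <- function(atlas, group_mixes, n_per_group = 3,
                                    noise_log2_sd = 0.15,
                                    experiment_tag = c("female_gsc_vs_kc",
                                                       "os_bgcn_vs_bgcn"),
                                    seed = 1) {
  experiment_tag <- match.arg(experiment_tag)
  if (!is.list(group_mixes) || length(group_mixes) != 2L ||
      is.null(names(group_mixes)) || any(names(group_mixes) == ""))
    stop("'group_mixes' must be a named list of exactly two mixture_designs",
         call. = FALSE)
  if (anyDuplicated(names(group_mixes)))
    stop("'group_mixes' must have two distinct group labels", call. = FALSE)
  if (n_per_group < 2L)
    stop("'n_per_group' must be >= 2 (downstream variance is undefined otherwise)",
         call. = FALSE)
  assert_count(n_per_group, "n_per_group", lower = 2L)
  assert_scalar_number(noise_log2_sd, "noise_log2_sd", lower = 0)
  assert_count(seed, "seed")

  mus <- lapply(group_mixes, function(d) mix_expression(atlas, d))
  n <- length(atlas$gene_ids)
  labels <- rep(names(group_mixes), each = n_per_group)
  mat <- with_seed(seed, {
    cols <- lapply(seq_along(labels), function(j) {
      mus[[labels[j]]] * 2^stats::rnorm(n, 0, noise_log2_sd)
    })
    do.call(cbind, cols)
  })
  dimnames(mat) <- list(atlas$gene_ids,
                        paste(labels, stats::ave(seq_along(labels), labels,
                                                 FUN = seq_along),
                              sep = "_"))
  structure(
    list(matrix = mat, group_labels = labels,
         experiment_tag = experiment_tag, gene_ids = atlas$gene_ids),
    class = "single_channel_set")
}

#' Partition atlas genes by planted truth class
#'
#' @param atlas a [build_atlas()] result.
#' @return Named list over all truth classes; each element is the character
#'   vector of gene ids in that class (length 0 for unused classes). The
#'   sets partition the gene universe.
#' @export
truth_sets <- function(atlas) {
  if (!inherits(atlas, "population_atlas"))
    stop("'atlas' must be a population_atlas", call. = FALSE)
  f <- factor(atlas$truth_class, levels = TRUTH_CLASSES)
  split(atlas$gene_ids, f)
}
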